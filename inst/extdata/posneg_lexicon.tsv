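token	polarity
good	1
great	1
excellent	1
amazing	1
wonderful	1
helpful	1
helped	1
support	1
supportive	1
encouraging	1
hopeful	1
hope	1
relief	1
relieved	1
better	1
best	1
improve	1
improved	1
improving	1
progress	1
grateful	1
thankful	1
thanks	1
appreciate	1
love	1
happy	1
glad	1
joy	1
calm	1
comfort	1
comfortable	1
positive	1
strong	1
recovery	1
healing	1
success	1
successful	1
kind	1
gentle	1
easier	1
safe	1
blessed	1
lucky	1
smile	1
laugh	1
enjoy	1
friend	1
friendly	1
welcome	1
useful	1
effective	1
beneficial	1
optimistic	1
motivated	1
proud	1
cheerful	1
pleasant	1
delighted	1
reassuring	1
uplifting	1
bad	-1
worse	-1
worst	-1
terrible	-1
horrible	-1
awful	-1
miserable	-1
painful	-1
hurt	-1
hurts	-1
ache	-1
suffer	-1
suffering	-1
sad	-1
depressed	-1
depressing	-1
anxious	-1
scared	-1
afraid	-1
fear	-1
worried	-1
worry	-1
hopeless	-1
helpless	-1
useless	-1
tired	-1
exhausted	-1
frustrated	-1
frustrating	-1
angry	-1
anger	-1
annoyed	-1
annoying	-1
hate	-1
cry	-1
crying	-1
tears	-1
lonely	-1
isolated	-1
fail	-1
failed	-1
failure	-1
sick	-1
nausea	-1
weak	-1
broken	-1
unbearable	-1
agony	-1
debilitating	-1
struggle	-1
struggling	-1
stress	-1
stressed	-1
stressful	-1
overwhelmed	-1
desperate	-1
dread	-1
grim	-1
bleak	-1
gloomy	-1
dreadful	-1
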