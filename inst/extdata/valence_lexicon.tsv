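token	valence
good	1.9
great	3.1
excellent	3.4
amazing	2.8
awesome	3.1
wonderful	2.7
fantastic	2.6
helpful	1.9
helped	1.7
helps	1.6
support	1.7
supportive	2.2
encouraging	2.3
hopeful	2.0
hope	1.9
relief	1.8
relieved	2.1
better	1.9
best	3.2
improve	1.6
improved	1.9
improving	1.8
progress	1.5
grateful	2.4
thankful	2.3
thanks	1.9
thank	1.7
appreciate	2.0
love	3.2
loved	2.9
happy	2.7
happiness	2.8
glad	2.0
joy	2.8
calm	1.3
comfort	1.5
comfortable	1.7
comforting	1.9
positive	2.0
strong	1.6
stronger	1.8
recovery	1.6
recovered	1.9
healing	1.8
healed	1.9
success	2.4
successful	2.5
win	2.6
working	1.2
works	1.4
worked	1.4
kind	1.8
kindness	2.2
gentle	1.4
manageable	1.2
bearable	1.0
easier	1.4
easy	1.5
safe	1.5
blessed	2.5
lucky	1.9
smile	1.8
laugh	2.0
enjoy	2.1
enjoyed	2.2
friend	1.6
friendly	1.9
welcome	1.7
useful	1.6
effective	1.8
beneficial	1.9
encouraged	2.0
optimistic	2.1
motivated	1.8
proud	2.1
bad	-2.5
worse	-2.1
worst	-3.1
terrible	-2.1
horrible	-2.5
awful	-2.0
miserable	-2.7
pain	-1.9
painful	-2.2
hurt	-2.4
hurts	-2.3
hurting	-2.2
ache	-1.7
aching	-1.8
suffer	-2.3
suffering	-2.5
suffered	-2.2
sad	-2.1
sadness	-2.3
depressed	-2.8
depressing	-2.6
depression	-2.7
anxious	-2.0
anxiety	-2.1
scared	-2.2
afraid	-2.0
fear	-1.9
worried	-1.8
worry	-1.7
worrying	-1.8
hopeless	-2.9
helpless	-2.5
useless	-2.3
tired	-1.4
exhausted	-2.0
exhausting	-1.9
frustrated	-2.2
frustrating	-2.1
frustration	-2.1
angry	-2.3
anger	-2.2
annoyed	-1.8
annoying	-1.8
hate	-2.7
hated	-2.5
cry	-2.0
crying	-2.1
tears	-1.7
lonely	-2.2
alone	-1.4
isolated	-2.0
lost	-1.5
fail	-2.3
failed	-2.4
failure	-2.5
sick	-1.9
sicker	-2.1
nausea	-1.7
dizzy	-1.4
weak	-1.7
weaker	-1.8
broken	-2.0
damage	-1.9
damaged	-2.0
unbearable	-2.9
agony	-3.0
agonizing	-3.0
debilitating	-2.6
disabling	-2.3
insomnia	-1.8
sleepless	-1.8
numb	-1.4
burning	-1.7
stabbing	-2.0
flare	-1.5
flares	-1.5
struggle	-2.0
struggling	-2.1
stress	-1.8
stressed	-1.9
stressful	-1.9
overwhelmed	-2.1
desperate	-2.4
dread	-2.3
grim	-2.0
bleak	-2.1
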