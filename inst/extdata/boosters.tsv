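token	increment
absolutely	0.293
completely	0.293
extremely	0.293
incredibly	0.293
really	0.293
so	0.293
totally	0.293
very	0.293
especially	0.293
particularly	0.293
unbelievably	0.293
hugely	0.293
barely	-0.293
hardly	-0.293
kinda	-0.293
kind_of	-0.293
marginally	-0.293
slightly	-0.293
somewhat	-0.293
sort_of	-0.293
a_bit	-0.293
a_little	-0.293
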