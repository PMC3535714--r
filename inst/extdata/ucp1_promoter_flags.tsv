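species	cgi_call	enhancer	prr
Human	high	yes	yes
Chimp	high	yes	yes
Orangutan	high	yes	yes
Macaque	high	yes	yes
Marmoset	high	no	no
Mouse Lemur	high	yes	yes
Tree Shrew	high	yes	yes
Pika	low	no	no
Rabbit	high	yes	yes
Guinea pig	high	yes	yes
Rat	low	yes	no
Mouse	absent	yes	no
Ground Squirrel	high	no	no
Shrew	low	no	no
Hedgehog	high	no	no
Mega Bat	high	yes	yes
Micro Bat	high	yes	no
Dog	high	yes	no
Cat	high	yes	no
Giant Panda	high	yes	yes
Horse	high	yes	yes
Cow	high	yes	yes
Pig	high	yes	no
Tenrec	high	yes	yes
Elephant	high	yes	yes
Opossom	low	no	no
Platypus	low	no	no
Xenopus	absent	no	no
Zebrafish	low	no	no
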