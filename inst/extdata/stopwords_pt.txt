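de
da
do
das
dos
e
a
o
em
para
com
por
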