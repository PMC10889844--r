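sample	cohort
Lb1	cultivated
Lb2	cultivated
Lb3	cultivated
Lb4	cultivated
Lb5	cultivated
Lb6w	wild
Lb7w	wild
Lb8w	wild
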