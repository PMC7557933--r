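>AtD90
AHCDHFLGEAPVYPCKEKACKSVCKEHYHHACKGECEYHGREVHCHCYGDYH
>AtD212
ANCDTYLGEVTVYYPCRERDCEAQCYEHYPHSCKGECEHHDHVVHHDNEEEHCHC
>CrD26
ANDCDRFLGEATVSYPCRERECEAQCHEHYEHSCKGECEDHDHDHGHHDHDDHHDHEEHC
HCYGH
>SlD26
AKHCGKHSKSWNGKCFHKKCNHWCMEKEDAKYGSCSHGDCYCYYHC
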