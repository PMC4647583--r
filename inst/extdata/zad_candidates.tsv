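# Candidate metabolite formulas for ion matching.
name	formula
ZAD-D	C54H83NO19
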