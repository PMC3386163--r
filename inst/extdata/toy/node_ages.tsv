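# node label	age_mya
AB	100
CD	150
Root	500
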