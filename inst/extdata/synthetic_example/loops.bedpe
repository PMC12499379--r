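chrS	57500	67500	chrS	407500	417500	loop1	.
chrS	57500	67500	chrS	282500	292500	loop2	.
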