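# Theoretically linked risk-factor words (example fixture).
trapped
crying
pain
alone
guilty
numb
anxiety
depression
lonely
worthless
burden
nightmare
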