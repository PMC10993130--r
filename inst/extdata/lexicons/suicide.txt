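# Suicide-specific phrase dictionary (example fixture).
kill myself
end it all
want to die
take my life
suicide
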