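# SYNTHETIC stand-in for an externally developed crisis-chat dictionary.
# The published dictionary (227 phrases) is not redistributable; this fixture
# keeps its three phrase families (suicidality states, crisis emotion states,
# behavior-related words) at fixture scale. Entries below the marker are
# synthetic placeholders, not drawn from the original list.
hurt myself
i just want this all to end
hate my life
hopeless
drown
rope
# --- synthetic placeholders ---
cannot go on
no way out
give up
overdose
goodbye forever
nothing matters
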