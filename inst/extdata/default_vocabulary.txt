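# Default predicate vocabulary for content triples.
# The predicate "include" is reserved for leaf-to-chunk structural edges
# and must not be listed here.
treats
composed_of
manifests_as
belongs_to
contraindicated_with
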