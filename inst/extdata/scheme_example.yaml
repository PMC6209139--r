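# Example point-scheme file for load_scheme().
#
# Equivalent to the built-in "mixed" scheme: the 7 clay marks and the
# medial eye canthus are fixed landmarks; the 22 remaining outline points
# are sliding semilandmarks (slider triples default to chords between
# outline neighbors). Indices run caudal -> rostral along the dorsum.
method_name: mixed_example
n_points: 30
landmarks: [1, 5, 9, 15, 22, 27, 28, 30]
subsets:
  dorsum: [1, 30]
  croup_back: [1, 15]
  neck_head: [15, 30]
derotation_triple: [1, 15, 30]
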