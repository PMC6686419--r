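# Original MMFF94s torsion parameters for the substructures addressed by
# this package, as quoted in the accompanying analysis. Only the N-aryl
# amide wildcard triple is quoted with numeric values; the original tables
# also contain records for the quadruples 0-37-39-0, 0-63-10-0 and
# 0-64-10-0, whose values are not reproduced here.
# TT I J K L V1 V2 V3
0 0 10 37 0 0.0 6.0 0.0
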