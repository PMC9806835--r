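14
synthetic cysteine seed (force-field-quality construction, not an ab initio minimum)
S    0.90172  -0.03113   0.11193
C    2.72603  -0.04143   0.08693
C    3.30613   1.21229   0.75139
N    2.90811   1.37175   2.18718
C    4.83782   1.18142   0.68303
O    5.50068   0.69208  -0.21968
O    5.38801   1.79982   1.76181
H    0.73310  -1.16420  -0.58862
H    3.05088  -0.10868  -0.95695
H    3.06968  -0.94943   0.59455
H    2.98992   2.11372   0.21246
H    3.12090   0.49498   2.67578
H    1.88042   1.39715   2.19679
H    4.63280   2.07913   2.33825
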