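8f0ab0a7dbdd19e957927931757f93c6 table1_coefficients.csv
395dffe94225d98ca4dd8eb299f78770 table2_esv.csv
4d90d6afa9da204e16b9237377bc1642 pi_coefficients.csv
a186e38830f96b769d5489cadbcd012d cnlucc_reclass.csv
5042e124b36dc922cd4828bc0d79d443 implied_areas.csv
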