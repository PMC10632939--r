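year,sex,prevalence_pct
2022,male,35.3
2025,male,34.0
2030,male,32.2
2035,male,30.7
2040,male,29.4
2045,male,28.3
2050,male,27.6
2022,female,3.6
2025,female,3.5
2030,female,3.3
2035,female,3.3
2040,female,3.2
2045,female,3.1
2050,female,3.1
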