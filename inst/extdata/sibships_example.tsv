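size	households	cases_among_siblings	households_single_case
1	167	167	167
2	163	154	129
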