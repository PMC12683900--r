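# Synthetic stand-in for a curated monogenic immune-disorder gene list.
# 30 symbols drawn from the synthetic genome's gene-naming scheme; used by
# the test-suite to exercise list parsing and precision-recall plumbing.
GENE0001
GENE0002
GENE0005
GENE0008
GENE0010
GENE0012
GENE0015
GENE0020
GENE0024
GENE0027
GENE0031
GENE0036
GENE0040
GENE0044
GENE0049
GENE0052
GENE0057
GENE0063
GENE0068
GENE0072
GENE0077
GENE0081
GENE0088
GENE0092
GENE0099
GENE0104
GENE0111
GENE0118
GENE0123
GENE0130
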