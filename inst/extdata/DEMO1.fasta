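>allele1
ATTGAATGGATTAGTAGATTGAATTAGATGCGAACAAAGGAACACGTACAAAGGTTCTCGATCAATGGATCTCGTTCAAT
GGTACACGAACTATGGTACTCGTACTATGGATCACGATCTAAGGTTCACGTTCTAAGGAACTAGGTCGAACATTGGTTCA
CGTACATTGGAACTCGATCATAGGTACTCGTTCATAGGATCACGAACTTAGGATCTCGTACTTAGGTACACGATCTTTGG
AACACGTTCTTTGGTTCTATTGAATAGATTGAAT
>allele2
ATTGAATGGATTAGTAGATTGAATTAGATGCGAACAAAGGAACACGTACAAAGGTTCTCGATCAATGGATCTCGTTCAAT
GGTACACGAACTATGGTACTCGTACTATGGATCACGATCTAAGGTTCACGTTCTAAGGAACTAGCTCGAACATTGGTTCA
CGTACATTGGAACTCGATCATAGGTACTCGTTCATAGGATCACGAACTTAGGATCTCGTACTTAGGTACACGATCTTTGG
AACACGTTCTTTGGTTCTATTGAATAGATTGAAT
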