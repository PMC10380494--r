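chrom	length_bp
Chr1	44825466
Chr2	29024987
Chr3	26387986
Chr4	25637364
Chr5	23141640
Chr6	21538263
Chr7	19226261
Chr8	17664456
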