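# Amplified-region bounds reported for the ODA14 xenograft at passage 2
# (dmin state), hg19 coordinates. The 40 kb chromosome-7 segment is reported
# as "40 kb in the 47.3 Mb region"; it is anchored at 47.30 Mb here. Other
# bounds are the printed Mb positions. 1-based inclusive.
chrom	start	end
chr7	47300001	47340000
chr7	54410001	55310000
chr8	127700001	129730000
chr8	130150001	132820000
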