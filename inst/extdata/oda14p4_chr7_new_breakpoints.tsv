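# New chromosome-7 breakpoints reported at passage 4 (hsr state) of the ODA14
# xenograft: single breakends or pairs/groups added to passage-2 clusters
# (status "existing") and newly formed clusters (status "new"). For the three
# members added to cluster Q only the bounding positions were published
# (55,279,982-55,280,274); the middle member's gap is interpolated (146,146)
# and marked synthetic here.
cluster	status	members	gaps	anchor
B	existing	a73		54559480
J	existing	b83		55125302
O	existing	a82		55262174
Q	existing	a83 b73 b80	146,146	55279982
R	new	a78 b77	35	54957228
S	new	b82 a80	103	55207419
T	new	a67 b68 a69 b75	209,37,1109	54438342
U	new	a85 b69 b74	11,19	55292438
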