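qtl,closest_marker,chr,pos_cM,lod,lower_bp,upper_bp,effect
SCS.qtl1,rs3658927,2,60.37,3.33,52795574,141957105,increase
SCS.qtl2,rs13478002,4,68.08,4.85,129338356,142748609,increase
SCS.qtl3,rs13478540,5,72.26,4.71,117927219,137110565,decrease
SCS.qtl4,rs13478841,6,34.74,5.42,51455318,87816657,increase
SCS.qtl5,rs13481127,11,48.5,4.41,45970896,91694862,increase
SCS.qtl6,mCV24625340,13,44.75,7.81,53171098,94326861,increase
SCS.qtl7,rs4160288,16,4.43,4.6,4326565,16886506,increase
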