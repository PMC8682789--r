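strain,prophage,contig,attL_start,attL_end,attR_start,attR_end,size,att_length
Pseudomonas aeruginosa PAO1,Pf4,NC_002516.2,785288,785336,797699,797747,12411,49
Shewanella oneidensis MR-1,CP4So,NC_004347.2,1501853,1501946,1538064,1538157,36211,94
Shewanella oneidensis MR-1,LambdaSo,NC_004347.2,3074594,3074605,3126435,3126446,51841,12
Escherichia coli K-12,rac,NZ_CP009273.1,1406156,1406198,1429216,1429258,23060,43
Listeria monocytogenes 10403S,Phi10403S,NC_017544.1,2319845,2319847,2357456,2357458,37611,3
Erythrobacter aquimaris SCSIO 43205,Pea1,chr,1888722,1888741,1936851,1936870,48129,20
Ruegeria conchae SCSIO 43209,Prc1,chr,1373446,1373460,1379997,1380011,6551,15
Halomonas meridiana SCSIO 43005,Phm1,chr,292609,292683,333351,333425,40742,75
Halomonas meridiana SCSIO 43005,Phm2,chr,1064123,1064145,1100156,1100178,36033,23
Halomonas meridiana SCSIO 43005,Phm3,chr,2090511,2090576,2139945,2140010,49434,66
Vibrio nigripulchritudo SCSIO 43132,Pvn1,contig1,353280,353303,367745,367768,14465,24
Marixanthomonas ophiurae SCSIO 43207,Pmo1,chr,2643352,2643371,2676198,2676217,32846,20
Mesoflavibacter sabulilitoris SCSIO 43206,Pms1,chr,2668021,2668042,2679241,2679262,11220,22
Zunongwangia mangrovi SCSIO 43204,Pzm1,chr,1472262,1472314,1512357,1512409,40095,53
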