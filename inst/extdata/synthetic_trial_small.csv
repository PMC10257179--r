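"animal_id","experiment_id","litter_id","treatment","sex","area_loss_pct"
"E01_A001","E01","E01_L02","HI/saline","male",23.75
"E01_A002","E01","E01_L01","HI/saline","female",46.97
"E01_A003","E01","E01_L02","HI/saline","male",51.88
"E01_A004","E01","E01_L01","HI/saline","female",24.76
"E01_A005","E01","E01_L01","HI/saline","male",33.82
"E01_A006","E01","E01_L03","HI/saline","female",39.23
"E01_A007","E01","E01_L01","HI/saline","male",36.86
"E01_A008","E01","E01_L02","HI/saline","female",67.74
"E01_A009","E01","E01_L03","HI/saline","male",54.91
"E01_A010","E01","E01_L03","HI/saline","female",44.23
"E01_A011","E01","E01_L01","HI/saline","male",47.31
"E01_A012","E01","E01_L02","HI/saline","female",23.62
"E01_A013","E01","E01_L03","HI/saline","male",56.15
"E01_A014","E01","E01_L01","HI/saline","female",47.4
"E01_A015","E01","E01_L01","melatonin","male",33.89
"E01_A016","E01","E01_L02","melatonin","female",36.39
"E01_A017","E01","E01_L01","melatonin","male",38.87
"E01_A018","E01","E01_L02","melatonin","female",29.94
"E01_A019","E01","E01_L02","melatonin","male",39.86
"E01_A020","E01","E01_L02","melatonin","female",10.89
"E01_A021","E01","E01_L01","melatonin","male",28.45
"E01_A022","E01","E01_L01","melatonin","female",17.22
"E02_A001","E02","E02_L01","HI/saline","male",49.81
"E02_A002","E02","E02_L02","HI/saline","female",39.66
"E02_A003","E02","E02_L01","HI/saline","male",27.53
"E02_A004","E02","E02_L02","HI/saline","female",48.27
"E02_A005","E02","E02_L02","HI/saline","male",30.29
"E02_A006","E02","E02_L02","HI/saline","female",41.72
"E02_A007","E02","E02_L01","HI/saline","male",54.7
"E02_A008","E02","E02_L01","HI/saline","female",27.91
"E02_A009","E02","E02_L02","HI/saline","male",47.82
"E02_A010","E02","E02_L02","melatonin","female",33.17
"E02_A011","E02","E02_L02","melatonin","male",38.79
"E02_A012","E02","E02_L02","melatonin","female",18.44
"E02_A013","E02","E02_L01","melatonin","male",6.72
"E02_A014","E02","E02_L01","melatonin","female",39.96
"E02_A015","E02","E02_L01","melatonin","male",9.25
"E02_A016","E02","E02_L02","melatonin","female",21.74
"E02_A017","E02","E02_L01","melatonin","male",33.6
"E02_A018","E02","E02_L02","melatonin","female",6.1
"E02_A019","E02","E02_L01","melatonin","male",32.01
"E03_A001","E03","E03_L01","HI/saline","male",29.54
"E03_A002","E03","E03_L03","HI/saline","female",39.11
"E03_A003","E03","E03_L02","HI/saline","male",11.9
"E03_A004","E03","E03_L02","HI/saline","female",48.92
"E03_A005","E03","E03_L01","HI/saline","male",54.95
"E03_A006","E03","E03_L01","HI/saline","female",49.75
"E03_A007","E03","E03_L01","HI/saline","male",51.6
"E03_A008","E03","E03_L02","HI/saline","female",66.59
"E03_A009","E03","E03_L02","HI/saline","male",39.39
"E03_A010","E03","E03_L02","HI/saline","female",31.81
"E03_A011","E03","E03_L01","HI/saline","male",23.82
"E03_A012","E03","E03_L01","HI/saline","female",32.34
"E03_A013","E03","E03_L02","HI/saline","male",40.1
"E03_A014","E03","E03_L01","melatonin","female",18.85
"E03_A015","E03","E03_L01","melatonin","male",19.36
"E03_A016","E03","E03_L02","melatonin","female",25.56
"E03_A017","E03","E03_L02","melatonin","male",17.83
"E03_A018","E03","E03_L01","melatonin","female",17.85
"E03_A019","E03","E03_L01","melatonin","male",13.07
"E03_A020","E03","E03_L01","melatonin","female",2.77
"E03_A021","E03","E03_L01","melatonin","male",11.92
"E03_A022","E03","E03_L01","melatonin","female",25.14
"E03_A023","E03","E03_L02","melatonin","male",24.15
"E03_A024","E03","E03_L01","melatonin","female",7
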