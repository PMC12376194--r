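analyte_id,benchmark_type,value_ugL,note
bromodichloromethane,MCLG,0,
bromodichloromethane,MCL,80,TTHM rule applies to the THM sum
bromoform,MCLG,0,
bromoform,MCL,80,TTHM rule applies to the THM sum
chloroform,MCLG,70,
chloroform,MCL,80,TTHM rule applies to the THM sum
dibromochloromethane,MCLG,60,
dibromochloromethane,MCL,80,TTHM rule applies to the THM sum
TTHM,MCLG,0,
TTHM,MCL,80,
d24,MCLG,70,
d24,MCL,70,
atrazine,MCLG,3,
atrazine,MCL,3,
simazine,MCLG,4,
simazine,MCL,4,
PFHxS,MCLG,0.01,
PFHxS,MCL,0.01,
PFNA,MCLG,0.01,
PFNA,MCL,0.01,
PFOA,MCLG,0,
PFOA,MCL,0.004,
PFOS,MCLG,0,
PFOS,MCL,0.004,
arsenic,MCLG,0,
arsenic,MCL,10,
barium,MCLG,2000,
barium,MCL,2000,
cadmium,MCLG,5,
cadmium,MCL,5,
chromium,MCLG,100,
chromium,MCL,100,
copper,MCLG,1300,
copper,MCL,1300,
lead,MCLG,0,
lead,MCL,15,non-health-based Action Level carried as MCL-type row
uranium,MCLG,0,
uranium,MCL,30,
fluoride,MCLG,4000,
fluoride,MCL,4000,
nitrate_N,MCLG,10000,
nitrate_N,MCL,10000,
lithium,HBSL,10,
manganese,HA,300,EPA lifetime health advisory
manganese,WHO_pGV,80,
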