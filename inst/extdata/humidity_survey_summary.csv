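rank,name,is_control,floral_structure,floral_type,grown_outside,mean_span_mm,span_n,stomata_pct,stomata_n,best_x_model,x_shape,comparable_x_models,best_z_model,z_shape,x_max_mm,x_max_replicate,delta_rh_max
1,Fuchsia sp.,FALSE,funnel,flower,TRUE,33.7,7,NA,NA,m0,F,,z2,F,0,(Z),0.05
NA,T control,TRUE,,,,NA,,NA,NA,m7,Q,,z1,L,-5.01,3,0.06
NA,TWLP control,TRUE,,,,NA,,NA,NA,m5,L,m5|m6,z2,F,-30,3,0.09
2,Nicotiana tabacum,FALSE,funnel,flower,FALSE,23.6,5,NA,NA,m2,Q,,z2,F,0,(Z),0.10
NA,TL control,TRUE,,,,NA,,NA,NA,m5,L,,z2,F,-30,3,0.10
NA,TLP control,TRUE,,,,NA,,NA,NA,m4,F,,z2,F,0,1,0.14
3,Vinca herbacea,FALSE,bell,flower,TRUE,48.6,12,0,5,m7,Q,,z0,F,-2.49,2,0.24
4,Allium ursinum,FALSE,unfused,flower,TRUE,20,a,NA,NA,m2,Q,,z2,F,0,(Z),0.24
5,Nepenthes sp.,FALSE,unfused,flower,FALSE,80,b,NA,NA,m2,Q,,z2,F,0,(Z),0.26
6,Papaver rhoeas,FALSE,unfused,flower,TRUE,56.4,9,100,5,m3,Q,,z2,F,-4.35,(Z),0.29
7,Euphorbia milii,FALSE,compound inflorescence,inflorescence,FALSE,12,c,NA,NA,m6,Q,,z2,F,0,3,0.29
8,Cyanus montanus,FALSE,compound inflorescence,inflorescence,TRUE,53.4,11,NA,NA,m7,Q,,z2,F,-1.88,2,0.31
9,Abutilon x milleri hort.,FALSE,funnel,flower,TRUE,30.8,6,0,4,m6,Q,,z2,F,0,1,0.32
10,Campanula sp.,FALSE,bell,flower,FALSE,20.7,3,NA,NA,m2,Q,,z2,F,0,(Z),0.36
11,Linum grandiflorum,FALSE,unfused,flower,TRUE,38,3,0,2,m10,Q,,z3,L,7.22,2,0.36
12,Geranium robertianum,FALSE,unfused,flower,TRUE,15.4,11,NA,NA,m2,Q,,z2,F,0,(Z),0.41
NA,TWL control,TRUE,,,,NA,,NA,NA,m2,Q,,z0,F,0,,0.46
13,Tulbaghia violacea,FALSE,funnel,flower,TRUE,29,9,NA,NA,m9,Q,,z2,F,0,1,0.52
14,Papaver cambricum,FALSE,unfused,flower,TRUE,48.3,8,100,5,m2,Q,,z1,L,0,,0.58
15,Bellis perennis,FALSE,compound inflorescence,inflorescence,TRUE,18.1,14,0,3,m2,Q,,z3,L,0,(Z),0.58
16,Epilobium hirsutum,FALSE,funnel,flower,TRUE,15.1,7,NA,NA,m2,Q,,z2,F,0,(Z),0.59
17,Trifolium pratense,FALSE,umbel inflorescence,inflorescence,TRUE,20.1,9,NA,NA,m9,Q,,z2,F,0,4,0.61
18,Lilium sp.,FALSE,funnel,flower,FALSE,93,5,NA,NA,m8,L,,z2,F,-30,4,0.65
19,Clematis chinensis,FALSE,unfused,flower,TRUE,50,d,NA,NA,m7,Q,,z2,F,-2.91,1,0.66
20,Cistus 'greyswood pink',FALSE,unfused,flower,TRUE,43.6,11,NA,NA,m2,Q,,z3,L,0,(Z),0.66
21,Cosmos bipinnatus,FALSE,compound inflorescence,inflorescence,FALSE,92.5,6,NA,NA,m7,Q,,z1,L,2.99,2,0.67
22,Geranium 'Roxanne',FALSE,unfused,flower,TRUE,42.6,8,0,4,m7,Q,,z3,L,-1.66,3,0.67
23,Potentilla sp.,FALSE,unfused,flower,TRUE,29,12,NA,NA,m7,Q,,z1,L,1.28,1,0.70
24,Coreopsis sp.,FALSE,compound inflorescence,inflorescence,FALSE,46.8,4,0,2,m3,Q,,z3,L,0.94,(Z),0.71
25,Lavandula angustifolia,FALSE,racemose inflorescence,inflorescence,TRUE,18.6,10,NA,NA,m6,Q,,z2,F,0,4,0.72
26,Geranium sanguineum,FALSE,unfused,flower,TRUE,41,12,NA,NA,m9,Q,,z3,L,0,2,0.79
27,Linum usitatissimum,FALSE,unfused,flower,TRUE,16.7,6,NA,NA,m9,Q,,z2,F,0,2,0.80
28,Convolvulus sabatius,FALSE,funnel,flower,TRUE,32.8,12,0,4,m9,Q,,z3,L,0,1,0.87
29,Cyanus segetum,FALSE,compound inflorescence,inflorescence,TRUE,36.4,14,NA,NA,m6,Q,,z0,F,0,1,1.10
NA,TW control,TRUE,,,,NA,,NA,NA,m2,Q,,z1,L,0,,1.17
30,Osteospermum sp.,FALSE,compound inflorescence,inflorescence,FALSE,51.9,10,20,5,m10,Q,,z4,L,5.49,3,1.20
31,Rudbeckia hirta,FALSE,compound inflorescence,inflorescence,TRUE,56.3,10,NA,NA,m7,Q,,z1,L,2.97,2,1.25
32,Scabiosa sp.,FALSE,compound inflorescence,inflorescence,FALSE,39.6,5,NA,NA,m3,Q,,z1,L,1.61,,1.36
33,Lantana sp.,FALSE,umbel inflorescence,inflorescence,FALSE,42.3,11,NA,NA,m2,Q,,z1,L,0,,1.47
34,Achillea millefolium,FALSE,umbel inflorescence,inflorescence,TRUE,33.3,9,NA,NA,m3,Q,,z1,L,1.69,,1.73
35,Leucanthemum vulgare,FALSE,compound inflorescence,inflorescence,TRUE,47.2,6,NA,NA,m7,Q,,z4,L,2.17,1,1.79
36,Oenothera caespitosa,FALSE,funnel,flower,FALSE,54.2,5,NA,NA,m10,Q,,z1,L,2.54,1,1.79
37,Ranunculus lingua,FALSE,unfused,flower,TRUE,35.7,7,NA,NA,m7,Q,,z3,L,2.61,2,3.16
38,Eschscholzia californica,FALSE,unfused,flower,TRUE,48.8,9,80,5,m7,Q,,z4,L,21.49,4,3.24
39,Taraxacum agg.,FALSE,compound inflorescence,inflorescence,TRUE,39.3,9,0,4,m9,Q,,z4,L,0,4,3.35
40,Ranunculus acris,FALSE,unfused,flower,TRUE,24,19,0,3,m9,Q,,z3,L,0,2,3.41
41,Xerochrysum bracteatum,FALSE,compound inflorescence,inflorescence,FALSE,48.4,9,0,3,m3,Q,,z1,L,1.41,,3.67
42,Calystegia silvatica,FALSE,funnel,flower,TRUE,61.8,12,NA,NA,m8,L,,z1,L,30,3,3.71
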