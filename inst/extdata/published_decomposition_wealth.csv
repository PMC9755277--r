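variable,category,row_type,elasticity,c_k,contribution,pct
mother_age_group,20-24,category,0.0350,0.0352,0.0012,1.02
mother_age_group,25-29,category,0.0181,-0.0124,-0.0002,-0.19
mother_age_group,30-49,category,0.0177,0.0279,0.0005,0.41
mother_age_group,total,total,,,0.0015,1.24
mother_education,primary,category,0.0829,-0.2753,-0.0228,-18.84
mother_education,secondary,category,0.2045,0.0362,0.0074,6.12
mother_education,higher,category,0.1093,0.4187,0.0457,37.78
mother_education,total,total,,,0.0303,25.06
wealth_quintile,poorer,category,0.0432,-0.3714,-0.0161,-13.25
wealth_quintile,middle,category,0.0279,0.0273,0.0008,0.63
wealth_quintile,richer,category,0.0391,0.4131,0.0161,13.32
wealth_quintile,richest,category,0.0731,0.8079,0.0591,48.77
wealth_quintile,total,total,,,0.0599,49.47
partner_education,primary,category,0.0065,-0.2098,-0.0014,-1.13
partner_education,secondary,category,0.0128,0.1319,0.0017,1.39
partner_education,higher,category,0.0265,0.4330,0.0115,9.49
partner_education,total,total,,,0.0118,9.75
residence,urban,category,0.0084,0.3970,0.0033,2.75
media_exposure,yes,category,-0.03654,-0.3669,0.0134,11.07
currently_working,yes,category,0.0513,-0.1770,-0.0091,-7.50
postnatal_visited,yes,category,0.1327,-0.0610,-0.0081,-6.69
anc_category,>=4,category,0.1210,0.2004,0.0242,20.01
child_sex,female,category,0.0362,-0.0059,-0.0002,-0.18
living_children_category,2,category,-0.0341,0.0263,-0.0009,-0.74
living_children_category,3+,category,-0.0097,-0.1457,0.0014,1.16
living_children_category,total,total,,,0.0005,0.42
division,chittagong,category,0.0118,0.0685,0.0008,0.67
division,dhaka,category,-0.0025,0.2778,-0.0007,-0.57
division,khulna,category,-0.0044,-0.0041,0.00002,0.02
division,mymensingh,category,0.0068,-0.2348,-0.0016,-1.32
division,rajshahi,category,-0.0044,-0.1066,0.0005,0.38
division,rangpur,category,0.0299,-0.2782,-0.0083,-6.87
division,sylhet,category,-0.0026,-0.0973,0.0003,0.21
division,total,total,,,-0.00898,-7.48
explained,,explained,,,0.11852,97.92
residual,,residual,,,0.00528,2.08
overall,,overall,,,0.1211,100
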