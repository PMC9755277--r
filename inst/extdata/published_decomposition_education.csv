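variable,category,row_type,elasticity,c_k,contribution,pct
mother_age_group,20-24,category,0.0345,0.0877,0.0031,2.29
mother_age_group,25-29,category,0.0181,-0.0296,-0.0005,-0.40
mother_age_group,30-49,category,0.0177,-0.1256,-0.0022,-1.65
mother_age_group,total,total,,,0.0005,0.24
mother_education,primary,category,0.0829,-0.6059,-0.0502,-37.43
mother_education,secondary,category,0.2045,0.1528,0.0312,23.28
mother_education,higher,category,0.1093,0.8206,0.0897,66.83
mother_education,total,total,,,0.0715,52.68
wealth_quintile,poorer,category,0.0432,-0.1550,-0.0067,-4.99
wealth_quintile,middle,category,0.0279,-0.0073,-0.0002,-0.15
wealth_quintile,richer,category,0.0391,0.1354,0.0053,3.94
wealth_quintile,richest,category,0.0731,0.3536,0.0259,19.27
wealth_quintile,total,total,,,0.0243,18.07
partner_education,primary,category,0.0065,-0.2039,-0.0013,-0.99
partner_education,secondary,category,0.0128,0.0868,0.0011,0.83
partner_education,higher,category,0.0265,0.5536,0.0147,10.95
partner_education,total,total,,,0.0145,10.79
residence,urban,category,0.0084,0.0698,0.0006,0.44
media_exposure,yes,category,-0.03654,-0.1970,0.0072,5.36
currently_working,yes,category,0.0513,-0.0822,-0.0042,-3.14
postnatal_visited,yes,category,0.1327,-0.0357,-0.0047,-3.54
anc_category,>=4,category,0.1210,0.1630,0.0197,14.69
child_sex,female,category,0.0362,0.0118,0.0004,0.32
living_children_category,2,category,-0.0341,0.0031,-0.0001,-0.08
living_children_category,3+,category,-0.0097,-0.2619,0.0025,1.88
living_children_category,total,total,,,0.0024,1.80
division,chittagong,category,0.0118,0.05,0.0006,0.44
division,dhaka,category,-0.0025,0.0079,-0.00002,-0.015
division,khulna,category,-0.0044,0.0484,-0.0002,-0.16
division,mymensingh,category,0.0068,-0.1035,-0.0007,-0.53
division,rajshahi,category,-0.0044,0.0081,-0.00004,-0.03
division,rangpur,category,0.0299,0.0556,0.0017,1.24
division,sylhet,category,-0.0026,-0.2030,0.0005,0.39
division,total,total,,,0.00184,1.34
explained,,explained,,,0.13404,99.05
residual,,residual,,,0.00012,0.95
overall,,overall,,,0.1341,100
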