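"person","age_years","stage","S_a1","S_a2","S_a3","S_a4","S_a5","S_a7","A_c1","A_c2","A_c3","A_c4","A_c5","A_c6","A_c7","A_g1","A_g2","A_g3","A_g4","A_g5","A_g6","A_g7","A_g8","A_g9","I_b1","I_b2","I_i","I_h5","I_f2","I_f1","I_e5","I_d3","I_d4","I_h3","I_f3","I_f4","I_h4","I_d1","I_e2","I_e3","I_e4","I_h2","I_e1","I_d2","I_d5","I_h1","I_d6","I_e6","I_e8","I_e7"
"P001",61,"III",2,3,2,3,4,2,1,1,1,1,0,0,0,1,1,1,1,1,0,0,0,0,3,2,1,0,1,0,0,0,0,1,1,0,0,1,1,1,0,1,1,1,1,0,0,0,0,0
"P002",76,"0-I",1,1,1,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,1,0,1,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,1,0
"P003",68,"II",1,3,3,2,4,2,1,1,1,1,0,0,0,1,1,0,1,0,0,0,0,0,1,2,2,1,0,1,1,1,1,0,0,1,1,0,0,1,1,0,0,1,0,0,0,1,0,0
"P004",63,"III",3,2,2,3,4,3,1,1,1,1,1,0,0,1,1,1,1,1,0,0,0,0,2,2,3,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,0,1,1,0,0,0
"P005",76,"II",1,0,1,0,2,1,1,0,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0,2,1,0,1,0,1,1,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,1,0,0
"P006",68,"III",4,3,2,3,4,2,1,1,1,1,1,0,0,1,1,1,1,0,0,0,0,0,2,3,3,1,1,1,1,1,1,1,1,0,1,1,0,1,0,1,1,1,0,1,1,0,1,1
"P007",70,"II",0,0,1,1,3,0,1,1,0,1,0,0,0,1,1,1,0,1,0,0,0,0,1,1,3,1,1,1,1,1,0,0,0,0,1,1,0,0,0,0,0,1,1,0,0,0,0,0
"P008",57,"III",2,0,1,2,2,1,1,1,0,1,1,0,0,1,1,1,1,0,0,0,0,0,1,2,1,0,0,1,1,0,0,0,0,1,1,1,0,0,1,0,0,0,0,0,1,0,0,0
"P009",68,"II",0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
"P010",77,"III",0,0,2,3,1,0,1,1,1,0,0,0,0,1,1,0,0,1,0,0,0,0,1,0,1,1,1,1,0,1,1,0,1,0,1,0,0,1,0,0,1,1,1,0,0,0,0,0
"P011",78,"II",0,0,1,0,2,2,1,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0
"P012",88,"III",4,4,3,4,4,3,1,1,1,1,1,0,0,1,1,1,1,0,0,0,0,0,2,2,3,1,1,1,1,1,1,1,1,1,0,0,0,1,0,1,1,0,1,1,1,1,0,0
"P013",72,"III",0,3,1,2,3,2,1,1,1,1,0,0,0,1,1,0,1,1,0,0,0,0,1,2,3,1,1,1,1,1,1,1,1,1,0,1,1,0,1,0,0,1,1,0,0,0,1,1
"P014",77,"III",2,2,2,3,3,1,1,1,1,0,1,0,0,0,1,0,0,0,0,0,0,0,0,3,1,1,1,0,1,1,1,1,1,0,0,0,1,1,0,0,0,0,0,1,1,0,0,0
"P015",66,"III",4,4,3,3,3,3,1,1,1,1,1,0,0,1,1,1,1,1,0,0,0,0,3,2,3,1,1,1,0,0,0,1,0,0,0,1,1,1,1,0,1,1,0,0,0,1,0,0
"P016",75,"III",2,3,2,3,3,3,1,1,1,1,0,0,0,1,1,1,1,0,0,0,0,0,1,3,3,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,0
"P017",74,"0-I",2,2,2,3,4,2,1,1,1,1,1,0,0,1,1,1,0,1,0,0,0,0,0,3,2,1,1,1,1,1,0,0,0,1,1,1,1,1,1,1,0,1,0,1,0,0,0,0
"P018",53,"IV",4,4,1,3,4,1,1,1,1,0,1,0,1,1,1,1,0,1,0,0,0,0,2,3,2,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,0,0,1,1,1,0,0
"P019",61,"II",4,4,4,4,4,3,1,1,1,1,1,0,0,1,1,1,1,1,1,0,0,0,3,3,3,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1
"P020",57,"II",4,4,3,3,4,1,1,1,1,1,1,0,0,1,1,1,0,0,0,1,0,0,0,1,2,1,1,1,1,1,0,1,1,0,1,1,1,1,1,1,1,1,1,0,0,1,0,0
"P021",76,"II",3,1,0,3,3,0,1,1,1,1,0,0,0,1,1,0,0,0,0,1,0,0,1,1,1,1,1,1,1,1,0,1,1,0,0,0,0,1,1,0,0,0,1,0,1,1,0,0
"P022",86,"III",3,3,3,4,3,3,1,1,1,1,1,1,0,1,1,1,1,1,0,0,1,0,2,3,2,1,1,1,0,1,0,1,1,1,0,1,1,0,1,1,1,1,0,1,0,0,1,1
"P023",66,"IV",2,1,3,4,3,2,1,1,1,0,0,0,1,1,1,1,1,1,0,1,0,1,1,2,3,1,1,1,0,1,1,1,0,1,1,1,1,0,1,1,1,1,0,0,0,1,0,0
"P024",85,"II",1,2,3,1,3,2,1,1,1,1,0,0,0,1,1,1,0,0,0,0,0,0,2,2,1,1,1,1,1,1,1,1,1,1,0,0,0,0,1,1,0,1,1,1,0,0,0,0
"P025",78,"II",1,0,1,2,2,1,0,1,1,1,0,0,0,1,1,1,1,0,0,0,0,0,0,2,2,1,1,1,0,0,1,0,1,1,1,0,1,1,1,0,0,0,0,1,0,0,0,0
"P026",76,"II",1,0,1,2,2,1,1,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,1,0,1,1,0,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0
"P027",71,"III",3,2,1,1,4,2,1,1,1,1,1,0,0,1,1,1,0,0,0,0,0,0,1,3,1,1,1,1,0,1,1,1,1,1,1,1,1,1,0,0,1,1,1,1,1,1,0,0
"P028",61,"III",2,4,2,1,4,3,1,1,1,1,0,0,0,1,1,1,1,1,1,1,0,0,1,3,3,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1,1,0,0,1,1,1
"P029",68,"II",2,4,3,3,4,2,1,1,1,1,1,1,0,1,1,1,1,1,0,0,1,0,3,2,3,1,1,1,1,1,1,1,1,1,0,1,1,1,1,0,1,1,1,0,1,1,0,1
"P030",80,"II",0,0,0,0,1,0,1,1,1,1,0,0,0,1,1,0,0,0,0,0,0,0,0,1,1,1,0,0,0,0,0,0,0,1,1,0,0,0,1,0,0,0,0,0,0,0,0,0
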