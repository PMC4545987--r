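items:
  S_a1:
    domain: Symptom
    n_categories: 5
    scale_group: sym_freq5
  S_a2:
    domain: Symptom
    n_categories: 5
    scale_group: sym_freq5
  S_a3:
    domain: Symptom
    n_categories: 5
    scale_group: sym_freq5
  S_a4:
    domain: Symptom
    n_categories: 5
    scale_group: sym_freq5
  S_a5:
    domain: Symptom
    n_categories: 5
    scale_group: sym_attack5
    reversed: yes
  S_a7:
    domain: Symptom
    n_categories: 4
    scale_group: sym_days4
  A_c1:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c2:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c3:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c4:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c5:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c6:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_c7:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g1:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g2:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g3:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g4:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g5:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g6:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g7:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g8:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  A_g9:
    domain: Activity
    n_categories: 2
    scale_group: act_bin
  I_b1:
    domain: Impact
    n_categories: 4
    scale_group: imp_b4
  I_b2:
    domain: Impact
    n_categories: 4
    scale_group: imp_b4
  I_i:
    domain: Impact
    n_categories: 4
    scale_group: imp_i4
    reversed: yes
  I_h5:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_f2:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_f1:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e5:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d3:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d4:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_h3:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_f3:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_f4:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_h4:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d1:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e2:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e3:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e4:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_h2:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e1:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d2:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d5:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_h1:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_d6:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e6:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e8:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
  I_e7:
    domain: Impact
    n_categories: 2
    scale_group: imp_bin
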