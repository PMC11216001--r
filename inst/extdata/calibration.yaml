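provenance:
  solver: data-raw/calibrate.R
  mc_draws_per_level: 200000
  solver_seed: 20240523
  solved: '2026-10-01'
  objective: 2.704719785148e-14
education_probs:
  Degree: 0.266266266266
  Highers: 0.319319319319
  UpperStdGrades: 0.26026026026
  LowerStdGradesNone: 0.154154154154
typology_mixing:
  Degree:
    ParentsFamilyFriends: 0.218230275176
    Grandparents: 0.283829617505
    PrivateGroup: 0.37157408352
    SingleProfessional: 0.126366023798
  Highers:
    ParentsFamilyFriends: 0.310232940372
    Grandparents: 0.368788030044
    PrivateGroup: 0.241398476102
    SingleProfessional: 0.079580553481
  UpperStdGrades:
    ParentsFamilyFriends: 0.429785427303
    Grandparents: 0.349360994202
    PrivateGroup: 0.154406136425
    SingleProfessional: 0.06644744207
  LowerStdGradesNone:
    ParentsFamilyFriends: 0.574850279286
    Grandparents: 0.275134642945
    PrivateGroup: 0.120389960826
    SingleProfessional: 0.029625116942
retention_rate: 0.61
attrition_coefs:
  intercept: 0.94697424564
outcome_coefs:
  intercept: -2.915192484496
  education:
    Degree: 0.0
    Highers: -0.071975137177
    UpperStdGrades: 0.418441660491
    LowerStdGradesNone: 0.333282164116
  typology:
    ParentsFamilyFriends: 0.0
    Grandparents: 0.060970699777
    PrivateGroup: -0.652909469792
    SingleProfessional: -0.105918123665
  interaction:
    Degree:
      ParentsFamilyFriends: 0.0
      Grandparents: 0.0
      PrivateGroup: 0.0
      SingleProfessional: 0.0
    Highers:
      ParentsFamilyFriends: 0.0
      Grandparents: 0.0
      PrivateGroup: 0.663252434502
      SingleProfessional: -0.466915039687
    UpperStdGrades:
      ParentsFamilyFriends: 0.0
      Grandparents: 0.0
      PrivateGroup: 0.506268277346
      SingleProfessional: -0.211272591131
    LowerStdGradesNone:
      ParentsFamilyFriends: 0.0
      Grandparents: 0.0
      PrivateGroup: 0.338788666791
      SingleProfessional: -0.110813328708
residual:
  marginal_y: 1.337980767846e-09
  ate_or: 1.94975990464e-07
  cde_private_or: 1.392950155221e-07
  cde_singleprof_or: 5.664251534476e-08
  rr: 4.515118823267e-08
implied:
  marginal_y: 0.109000001338
  ate_or:
  - 1.352000108741
  - 2.596000194976
  - 3.18100015483
  cde_private_or:
  - 2.163999874025
  - 3.599999860705
  - 3.777999946201
  cde_singleprof_or:
  - 0.712999987258
  - 1.781999943357
  - 2.419999964954
  rr:
  - 1.052000025094
  - 0.832000034733
  - 0.770000045151
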