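# Dithionite-trap O2 dissociation assay for the two-heme globin:
# triplicates at three trap concentrations.
seed: 20201119
protein:
  name: WT1
  sites:
    - has_distal_his: true
      k_minus_H_per_s: 126
      k_H_per_s: 500
      k_prime_on_NO_per_M_s: 5.0e+9
      k_on_O2_per_M_s: 1.0e+9
      k_off_O2_per_s: 0.319
      k_on_CO_per_M_s: 1.17e+6
      k_NOD_per_M_s: 7.0e+7
      k_NiR_pH7_per_M_s: 363
    - has_distal_his: true
      k_minus_H_per_s: 126
      k_H_per_s: 500
      k_prime_on_NO_per_M_s: 5.0e+9
      k_on_O2_per_M_s: 1.0e+9
      k_off_O2_per_s: 0.190
      k_on_CO_per_M_s: 1.32e+5
      k_NOD_per_M_s: 7.0e+7
      k_NiR_pH7_per_M_s: 363
assays:
  - kind: O2_dissociation_trap
    label: wt1_trap
    protein_conc_M: 2.5e-6
    vary: dithionite_conc
    values_M: [6.75e-3, 1.35e-2, 2.75e-2]
    n_replicates: 3
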