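# Demonstration run: two simulated interneuron groups under an antagonist
# (events abolished after the drug, outward baseline shift), group-level
# tonic currents 22.5 pA vs 9.1 pA, n = 7 vs 7. Between-cell dispersions
# are standard deviations (SEM * sqrt(n) scale).
seed: 101
mode: antagonist
simulation:
  groups:
    - label: PV
      n_cells: 7
      condition: SR95531
      config:
        duration_s: 160
        t_drug_s: 20
        i_hold_pa: -45
        tonic_shift_pa: 22.5
        post_drug_event_scale: 0
        capacitance_pf: 68
      dispersion:
        tonic_shift_pa: 6.1
        i_hold_pa: 23.8
        capacitance_pf: 8
    - label: SST
      n_cells: 7
      condition: SR95531
      config:
        duration_s: 160
        t_drug_s: 20
        i_hold_pa: -68
        tonic_shift_pa: 9.1
        post_drug_event_scale: 0
        capacitance_pf: 65
      dispersion:
        tonic_shift_pa: 6.1
        i_hold_pa: 23.8
        capacitance_pf: 8
analysis:
  post_delay_s: 120
compare:
  variables:
    - tonic_current_pa
    - current_density_pa_per_pf
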