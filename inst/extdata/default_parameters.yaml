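costs:
  item:
  - psa_test
  - stockholm3
  - mri
  - biopsy
  - rp
  - rt
  - plnd
  - adt
  - arpi
  - chemo_cycle
  - immune
  - parp
  - lu_psma
  - ra223
  - psma_pet
  - osteoprotective
  - palliative
  - end_of_life
  - trus
  unit_cost:
  - 29.0
  - 400.0
  - 406.0
  - 1347.0
  - 10832.0
  - 7726.0
  - 1500.0
  - 2370.0
  - 8905.0
  - 15519.0
  - 104264.0
  - 51216.0
  - 90106.0
  - 25692.0
  - 1498.0
  - 1058.0
  - 27980.0
  - 13939.0
  - 100.0
  sd:
  - 12.0
  - .na.real
  - 169.0
  - 1540.0
  - 3464.0
  - 3334.0
  - .na.real
  - 1413.0
  - 18886.0
  - 9476.0
  - 28046.0
  - 15444.0
  - 36598.0
  - 5825.0
  - 1209.0
  - 1031.0
  - 16067.0
  - 13179.0
  - .na.real
  basis:
  - per_event
  - per_event
  - per_event
  - per_event
  - per_event
  - per_event
  - per_event
  - per_year
  - per_year
  - total_course
  - per_year
  - per_year
  - per_year
  - per_year
  - per_event
  - per_year
  - total_course
  - total_course
  - per_event
config:
  horizon_years: 6
  discount_rate: 0.03
  cycle_length: 1.0
  cohort_size: 1000.0
strategies:
  psa_mri:
    strategy: psa_mri
    p_psa_ge_3: 0.3
    p_psa_ge_1_5: 0.446708333333333
    p_sthlm3_pos: .na.real
    p_high_risk: .na.real
    p_pirads_pos: 0.516515242573149
    biopsy_outcome:
      benign: 0.382420187668791
      isup1: 0.172022562726088
      isup2_5: 0.361661693846771
      metastatic: 0.08389555575835
    fn_cs_per_1000: 0.0
    fn_progress: 0.0
  sthlm3_reflex:
    strategy: sthlm3_reflex
    p_psa_ge_3: 0.3
    p_psa_ge_1_5: 0.446708333333333
    p_sthlm3_pos: 0.55964928644716
    p_high_risk: .na.real
    p_pirads_pos: 0.597893025064517
    biopsy_outcome:
      benign: 0.365738886848882
      isup1: 0.096298622411251
      isup2_5: 0.464905943550198
      metastatic: 0.073056547189669
    fn_cs_per_1000: 0.0
    fn_progress: 0.0
  swop:
    strategy: swop
    p_psa_ge_3: 0.3
    p_psa_ge_1_5: 0.446708333333333
    p_sthlm3_pos: .na.real
    p_high_risk: 0.411923235065718
    p_pirads_pos: 0.575257531987717
    biopsy_outcome:
      benign: 0.140669564195918
      isup1: 0.112489298123193
      isup2_5: 0.563970704226195
      metastatic: 0.182870433454693
    fn_cs_per_1000: 15.94925500062072
    fn_progress: 0.1
mix:
  arpi_fraction: 0.8
  triplet_given_arpi_fraction: 0.25
  taxane_only_fraction: 0.2
  parp_fraction: 0.09
  immune_fraction: 0.01
  radiopharm_fraction: 0.3
  radiopharm_lu_split: 0.5
  osteoprotective_fraction: 0.33
  palliative_fraction: 0.5
  eol_fraction: 0.35
  discontinuation_year1: 0.3
  discontinuation_increment: 0.1
  adt_years: 6.0
as_sched:
  cum_progression:
    '3': 0.25
    '5': 0.35
  events:
    year:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    psa:
    - 3.0
    - 2.0
    - 2.0
    - 2.0
    - 2.0
    - 2.0
    mri:
    - 1.0
    - 0.0
    - 1.0
    - 0.0
    - 1.0
    - 0.0
    biopsy:
    - 1.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
  curative_mix:
    rp: 0.5
    rt_short_adt: 0.5
loc_mix:
  intermediate_fraction: 0.6
  intermediate_weights:
    rp: 0.5
    rt_adt: 0.5
  high_weights:
    rp_plnd: 0.5
    rt_adt: 0.5
  adt_years_intermediate: 1.0
  adt_years_high: 3.0
migration:
  isup1: 0.54
  isup2_5: 1.24
  metastatic: 0.84
multipliers:
  isup1: 1.261017364313868
  isup2_5: 0.620675569666671
  metastatic: 4.86005331493367
scales:
  cost:
    diagnostic: 1.0
    isup1: 1.0
    isup2_5: 1.0
    metastatic: 1.0
  count:
    isup1: 1.0
    isup2_5: 1.0
  migration_mpc: 1.0
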