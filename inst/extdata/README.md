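# Bundled example data

- `synthetic_treatment_means.csv` — a SYNTHETIC table of 21 treatment
  means from 8 fictitious studies (5 TMR, 3 pasture), produced by
  `simulate_study_table(sim_config(seed = 421, n_studies = c(TMR = 5,
  PASTURE = 3), means_per_study = c(2, 3)))` and rounded to 3 decimals.
  It exists so examples and file-reading code have a small well-formed
  input; it is not literature data and carries no empirical content.

Column layout (see `study_table_schema()` for the full description):

| column          | unit        | required |
|-----------------|-------------|----------|
| study_id        | DOI string  | yes      |
| diet            | TMR/PASTURE | yes      |
| un_gd           | g/d         | yes      |
| un_sem          | g/d         | when weighting |
| mun_mgdl        | mg/dL       | yes      |
| bw_kg           | kg          | yes      |
| dmi_kg          | kg/d        | yes      |
| cp_pct          | % of DM     | yes      |
| ndf_pct         | % of DM     | no       |
| n_intake_gd     | g/d         | no       |
| milk_yield_kgd  | kg/d        | no       |
| dim_d           | d           | no       |
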