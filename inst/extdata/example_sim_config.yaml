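# Example synthetic-crash configuration.
# Severity is generated from a three-level logit with Gumbel errors; any
# coefficient listed under spec/random varies across crashes as
#   beta = mean + delta'Z + sd * exp(omega'W) * nu,   nu ~ N(0, 1).
# Parameter names follow param_template(): "LEVEL:term", "sd(LEVEL:term)",
# "LEVEL:term|mean:Z", "LEVEL:term|sd:W".
n_crashes: 500
seed: 7
covariates:
  - {name: male_driver, group: driver, prevalence: 0.5}
  - {name: sudden_slowing, group: driver, prevalence: 0.5}
  - {name: wet_surface, group: roadway, prevalence: 0.5}
  - {name: occ_restraints, group: occupant, prevalence: 0.85}
spec:
  base: PDO
  fixed:
    I: ["(Intercept)", male_driver, wet_surface]
    FI: ["(Intercept)"]
  random:
    - term: occ_restraints
      level: I
      mean_shifters: [sudden_slowing]
params:
  "I:(Intercept)": -0.6
  "I:male_driver": -0.3
  "I:wet_surface": 0.4
  "FI:(Intercept)": -6.0
  "I:occ_restraints": -1.5
  "sd(I:occ_restraints)": 1.0
  "I:occ_restraints|mean:sudden_slowing": -0.55
years:
  - {year: 2017}
  - {year: 2018, shift: {"I:male_driver": 0.0}}
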