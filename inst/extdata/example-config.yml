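# Example pipeline configuration for ltcasim::read_ltca_config().
# Every key maps to an argument of ltca_config(); the master seed is
# expanded deterministically into per-stage seeds, so this file fully
# determines all outputs.

# synthetic starting population (65+ stock in the base year)
n_individuals: 10000        # persons in the base-year stock
base_year: 2025             # first simulated calendar year
# care-need survey used to estimate the two logit equations
survey_n: 20000             # survey respondents
degree: 2                   # age-polynomial degree of both equations
# simulation horizon and cohort entry
horizon: 2080               # last simulated calendar year
entry_rate: 0.05            # first entry cohort as share of the stock
entry_growth: 1.002         # multiplicative annual cohort-size growth
expansion: true             # educational expansion in entry cohorts
# mortality
annual_improvement: 0.985   # hazard multiplier per calendar year
# reproducibility
seed: 1                     # master RNG seed
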