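# Shared seeded fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, maker(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the study-condition cohort: 200 acceptors, 30% sensitive, psi = 0.5,
# 16 MUT vs 56 WT
default_cohort <- function() cached_fixture("default", function()
  generate_cohort(synthetic_config(seed = 7L)))

# null cohort for calibration: psi = 0, 2,000 junctions, mu = 100
null_cohort <- function() cached_fixture("null", function()
  generate_cohort(synthetic_config(seed = 3L, n_acceptors = 2000L,
                                   sensitive_fraction = 0, nb_mean = 100)))

# 2,000 planted AG' sites for composition checks (sample size irrelevant)
agprime_cohort <- function() cached_fixture("agprime", function()
  generate_cohort(synthetic_config(seed = 11L, n_acceptors = 2000L,
                                   sensitive_fraction = 1, n_mut = 1L,
                                   n_wt = 1L, mutant_fractions = 0.5)))

toy_genome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}

sensitive_truth <- function(cohort) cohort$truth[cohort$truth$sensitive, ]

alt_sites_of <- function(cohort, truth = sensitive_truth(cohort)) {
  acceptor_of(cohort$junctions[match(truth$alt_junction, cohort$junctions$id), ])
}

can_sites_of <- function(cohort, truth = sensitive_truth(cohort)) {
  acceptor_of(cohort$junctions[match(truth$can_junction, cohort$junctions$id), ])
}
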