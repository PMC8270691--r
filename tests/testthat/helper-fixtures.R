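# Shared fixtures: small cohorts and hand-built tables used across test files.

small_cohort <- function(seed = 1, ...) {
  defaults <- list(n_patients = 20, visits_min = 4, visits_max = 6,
                   n_healthy = 10, n_genes = 200, n_activity_genes = 20,
                   ifn_module_size = 10, ne_module_size = 10, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  generate_cohort(do.call(sim_config, args))
}

# A minimal hand-built clinical table (2 patients x visits + healthy).
toy_clinical <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P2", "H1"),
    sample_id = paste0("s", 1:7),
    visit_index = c(0L, 1L, 2L, 0L, 1L, 2L, 0L),
    time_days = c(0, 60, 120, 0, 91.32, 182.64, 0),
    sledai = c(4, 8, 6, 10, 8, 6, 0),
    state = c(rep("SLE", 6), "healthy"),
    age_group = "adult", sex = "female", race = "white",
    drug_cs = FALSE, drug_hc = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    drug_is = FALSE, drug_ifnk = FALSE, cohort = "cohortA",
    stringsAsFactors = FALSE
  )
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1)),
              label = sprintf("max rel err %.3g", max(abs(x - y) / pmax(abs(y), 1))))
}
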