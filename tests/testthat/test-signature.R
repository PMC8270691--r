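test_that("two-group ANOVA F equals the squared pooled t statistic", {
  m <- rbind(g1 = c(5, 6, 7, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  clin <- data.frame(
    patient_id = paste0("P", 1:6), sample_id = colnames(m),
    visit_index = 0L, time_days = 0,
    sledai = c(5, 5, 5, 0, 0, 0),
    state = rep(c("SLE", "healthy"), each = 3),
    age_group = "adult", sex = "female", race = "white",
    drug_cs = FALSE, drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE,
    cohort = "A", stringsAsFactors = FALSE)
  screen <- anova_screen(m, clin)
  tt <- t.test(c(5, 6, 7), c(1, 2, 3), var.equal = TRUE)
  expect_equal(screen$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(screen$p_value, tt$p.value, tolerance = 1e-12)
  # identical values in both groups: F = 0, p = 1
  m0 <- rbind(g1 = rep(2, 6)); colnames(m0) <- colnames(m)
  s0 <- anova_screen(m0, clin)
  expect_equal(s0$f_stat, 0)
  expect_equal(s0$p_value, 1)
})

test_that("ANOVA screen agrees with stats::oneway.test over random genes", {
  coh <- small_cohort(31, n_patients = 10, n_genes = 20,
                      n_activity_genes = 4, ifn_module_size = 4,
                      ne_module_size = 4)
  screen <- anova_screen(coh$expression, coh$clinical)
  state <- coh$clinical$state[match(colnames(coh$expression),
                                    coh$clinical$sample_id)]
  for (i in c(1, 7, 20)) {
    ref <- oneway.test(coh$expression[i, ] ~ state, var.equal = TRUE)
    expect_equal(screen$f_stat[i], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(screen$p_value[i], ref$p.value, tolerance = 1e-9)
  }
})

test_that("patient weights are proportional to visit counts", {
  clin <- toy_clinical()
  clin <- rbind(clin, within(clin[1:3, ], {
    patient_id <- "P3"; sample_id <- paste0("x", 1:3)
    sledai <- c(2, 6, 4)
  }))
  # P1: 3 visits, P2: 3 visits, P3: 3 visits -> uniform
  w <- patient_weights(clin)
  expect_equal(unname(w[c("P1", "P2", "P3")]), rep(1 / 3, 3))
  # 4 vs 8 visits -> 1/3, 2/3
  mk <- function(p, n) data.frame(
    patient_id = p, sample_id = paste0(p, "_", 1:n), visit_index = 0:(n - 1),
    time_days = (0:(n - 1)) * 30, sledai = (1:n) %% 5 + 1, state = "SLE",
    age_group = "adult", sex = "female", race = "white", drug_cs = FALSE,
    drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE, cohort = "A",
    stringsAsFactors = FALSE)
  w2 <- patient_weights(rbind(mk("A", 4), mk("B", 8)))
  expect_equal(unname(w2[c("A", "B")]), c(1 / 3, 2 / 3))
  # below min_visits -> weight 0
  w3 <- patient_weights(rbind(mk("A", 2), mk("B", 8)))
  expect_equal(unname(w3["A"]), 0)
})

test_that("activity score reaches 1 for perfect monotone tracking", {
  clin <- toy_clinical()
  m <- rbind(gA = c(4, 8, 6, 10, 8, 6, 1),      # equals SLEDAI within patients
             gB = c(1, 2, 3, 5, 1, 4, 2))
  colnames(m) <- clin$sample_id
  w <- patient_weights(clin)
  sc <- activity_score(m, clin, c("gA", "gB"), w)
  expect_equal(unname(sc$score["gA"]), 1)
  expect_lt(sc$score["gB"], 1)
  expect_error(activity_score(m, clin, "missing_gene", w), "missing_gene")
})

test_that("score is invariant to joint within-patient reordering", {
  coh <- small_cohort(32, n_patients = 8, n_genes = 30,
                      n_activity_genes = 5, ifn_module_size = 5,
                      ne_module_size = 5)
  clin <- coh$clinical
  w <- patient_weights(clin)
  genes <- rownames(coh$expression)[1:10]
  s1 <- activity_score(coh$expression, clin, genes, w)$score
  # shuffle the visit rows of the clinical table (joint reorder: the
  # sample_id linkage keeps expression and SLEDAI together)
  set.seed(1)
  clin2 <- clin[sample(nrow(clin)), ]
  s2 <- activity_score(coh$expression, clin2, genes, w)$score
  expect_equal(s1, s2)
})

test_that("spearman score is invariant to monotone expression transforms", {
  coh <- small_cohort(33, n_patients = 8, n_genes = 30,
                      n_activity_genes = 5, ifn_module_size = 5,
                      ne_module_size = 5)
  w <- patient_weights(coh$clinical)
  genes <- rownames(coh$expression)[1:10]
  s1 <- activity_score(coh$expression, coh$clinical, genes, w)$score
  s2 <- activity_score(exp(coh$expression / 2), coh$clinical, genes, w)$score
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("null genes score below strongly tracked genes", {
  coh <- small_cohort(34, n_patients = 12, visits_min = 5, visits_max = 8,
                      n_genes = 150, n_activity_genes = 15,
                      activity_cor = 0.85)
  w <- patient_weights(coh$clinical)
  null_genes <- setdiff(rownames(coh$expression),
                        c(coh$truth$activity_genes, coh$truth$ifn_genes,
                          coh$truth$ne_genes))[1:50]
  s_null <- activity_score(coh$expression, coh$clinical, null_genes, w)$score
  s_act <- activity_score(coh$expression, coh$clinical,
                          coh$truth$activity_genes, w)$score
  expect_lt(mean(s_null), 0.4)
  expect_gt(mean(s_act), mean(s_null) + 0.2)
})

test_that("permutation p-values respect the add-one estimator bounds", {
  coh <- small_cohort(35, n_patients = 8, n_genes = 40, activity_cor = 0.9)
  w <- patient_weights(coh$clinical)
  genes <- c(coh$truth$activity_genes[1:5],
             setdiff(rownames(coh$expression), coh$truth$activity_genes)[1:5])
  pc <- permutation_calibration(coh$expression, coh$clinical, genes, w,
                                n_perm = 50, seed = 2)
  expect_true(all(pc$perm_p >= 1 / 51))
  expect_true(all(pc$perm_p <= 1))
  # a strongly tracked gene saturates the estimator at the lower bound
  expect_equal(unname(min(pc$perm_p[coh$truth$activity_genes[1:5]])), 1 / 51)
})

test_that("random gene-set comparison separates planted signal", {
  coh <- small_cohort(36, n_patients = 15, visits_min = 5, visits_max = 8,
                      n_genes = 300, n_activity_genes = 20,
                      activity_cor = 0.85)
  w <- patient_weights(coh$clinical)
  rc <- random_geneset_comparison(coh$expression, coh$clinical,
                                  coh$truth$activity_genes, w,
                                  n_random = 100, seed = 3)
  expect_lte(rc$p, 0.02)
  # add-one arithmetic at n_random = 1
  rc1 <- random_geneset_comparison(coh$expression, coh$clinical,
                                   coh$truth$activity_genes, w,
                                   n_random = 1, seed = 3)
  expect_equal(rc1$p, 0.5)
})

test_that("signature selection applies strict thresholds and sorts by score", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    q_value = c(0.01, 0.01, 0.2, 0.01),
                    score = c(0.7, 0.6, 0.9, 0.65))
  sel <- select_signature(res)
  expect_equal(sel, c("a", "d"))           # b fails strict >, c fails q
  # selection shrinks monotonically as score_min rises
  sizes <- suppressWarnings(
    vapply(c(0, 0.3, 0.6, 0.9),
           function(s) length(select_signature(res, score_min = s)),
           integer(1)))
  expect_true(all(diff(sizes) <= 0))
  expect_warning(select_signature(res, score_min = 1), "no genes")
})
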