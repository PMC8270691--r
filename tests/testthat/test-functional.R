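make_clin <- function(ids, states) {
  data.frame(
    patient_id = paste0("P", seq_along(ids)), sample_id = ids,
    visit_index = 0L, time_days = 0,
    sledai = ifelse(states == "healthy", 0, 6), state = states,
    age_group = "adult", sex = "female", race = "white", drug_cs = FALSE,
    drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE, cohort = "A",
    stringsAsFactors = FALSE)
}

test_that("GED activity recovers a planted shift and the Gaussian null", {
  set.seed(21)
  n_h <- 40; n_s <- 5; n_g <- 60
  m <- matrix(rnorm(n_g * (n_h + n_s)), n_g,
              dimnames = list(paste0("g", 1:n_g),
                              paste0("x", 1:(n_h + n_s))))
  states <- c(rep("healthy", n_h), rep("SLE", n_s))
  clin <- make_clin(colnames(m), states)
  gs <- geneset_collection("T1", list(paste0("g", 1:20)), module = "IFN")
  # shift the term genes by +3 sd in the first SLE sample
  sick <- colnames(m)[n_h + 1]
  m[1:20, sick] <- m[1:20, sick] + 3
  act <- ged_activity(m, clin, gs)
  expect_equal(unname(act$activity["T1", sick]), 3, tolerance = 0.45)
  # unshifted SLE samples sit at the E|Z| null level
  others <- colnames(m)[(n_h + 2):(n_h + n_s)]
  expect_equal(mean(act$activity["T1", others]), sqrt(2 / pi),
               tolerance = 0.15)
  expect_true(all(act$activity >= 0))
})

test_that("zero-variance healthy genes are dropped with a warning", {
  set.seed(22)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("x", 1:10)))
  m[1, 1:8] <- 5   # constant across the healthy reference
  clin <- make_clin(colnames(m), c(rep("healthy", 8), "SLE", "SLE"))
  gs <- geneset_collection("T1", list(paste0("g", 1:6)))
  expect_warning(act <- ged_activity(m, clin, gs), "zero healthy variance")
  # term still computed from the remaining genes
  expect_equal(nrow(act$activity), 1L)
  # a term left with < 3 genes is dropped
  gs2 <- geneset_collection(c("T1", "T2"),
                            list(paste0("g", 1:6), c("g1", "g2", "g3")))
  m2 <- m; m2[2, 1:8] <- 1
  expect_warning(expect_warning(act2 <- ged_activity(m2, clin, gs2),
                                "zero healthy variance"), "dropped")
  expect_equal(act2$term_ids, "T1")
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  background <- paste0("g", 1:100)
  term <- paste0("g", 1:10)
  query <- paste0("g", c(1:4, 50:55))   # overlap k = 4, n = 10
  gs <- geneset_collection("T1", list(term))
  res <- enrich_terms(query, gs, background)
  # brute-force tail over the hypergeometric support
  p_brute <- sum(vapply(4:10, function(x) {
    choose(10, x) * choose(90, 10 - x) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p_value, p_brute, tolerance = 1e-9)
  # disjoint term -> p = 1; the query's own term is the most enriched
  gs2 <- geneset_collection(c("self", "disjoint"),
                            list(query, paste0("g", 80:90)))
  res2 <- enrich_terms(query, gs2, background)
  expect_equal(res2$p_value[res2$term_id == "disjoint"], 1)
  expect_equal(res2$term_id[which.min(res2$p_value)], "self")
  expect_error(enrich_terms(query, gs, character(0)), "background")
})

test_that("per-subtype DEG screen recovers the planted module genes", {
  coh <- small_cohort(61, n_patients = 24, n_healthy = 15,
                      ifn_module_size = 15, ne_module_size = 15)
  labels <- coh$truth$subtype_of_sample
  labels <- labels[!is.na(labels)]
  degs <- subtype_deg(coh$expression, labels, coh$clinical)
  ifn_hits <- degs[["IFN-high"]]
  expect_gte(mean(coh$truth$ifn_genes %in% ifn_hits$gene[ifn_hits$deg]), 0.9)
  # the mixed subtype is dysregulated in both modules
  mx <- degs[["mixed"]]
  expect_gte(mean(c(coh$truth$ifn_genes, coh$truth$ne_genes) %in%
                    mx$gene[mx$deg]), 0.9)
})

test_that("module profile ranks the planted module highest in its subtype", {
  coh <- small_cohort(62, n_patients = 30, n_healthy = 20)
  gs <- build_term_collection(coh$truth, rownames(coh$expression), seed = 62)
  act <- suppressWarnings(ged_activity(coh$expression, coh$clinical, gs))
  labels <- coh$truth$subtype_of_sample
  labels <- labels[!is.na(labels)]
  prof <- module_profile(act, labels, coh$clinical)
  ne <- prof[prof$subtype == "NE-high" & prof$module != "immune", ]
  expect_true(ne$module[which.max(ne$delta)] %in% c("bacterial", "fungal"))
  expect_lt(ne$p_value[ne$module == "bacterial"], 0.001)
  # mixed is at least as dysregulated as the matching single-module subtype
  for (m in c("viral", "IFN", "bacterial", "fungal")) {
    d_mixed <- prof$delta[prof$subtype == "mixed" & prof$module == m]
    single <- if (m %in% c("viral", "IFN")) "IFN-high" else "NE-high"
    d_single <- prof$delta[prof$subtype == single & prof$module == m]
    expect_gt(d_mixed, d_single)
  }
})

test_that("term similarity is symmetric with unit diagonal", {
  coh <- small_cohort(63, n_patients = 10, visits_min = 3, visits_max = 3)
  gs <- build_term_collection(coh$truth, rownames(coh$expression), seed = 63)
  act <- suppressWarnings(ged_activity(coh$expression, coh$clinical, gs))
  ids <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
  S <- term_similarity(act, ids)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= -1 & S <= 1))
  expect_error(term_similarity(act, ids[1:5]), ">= 10")
})

test_that("network edges respect the threshold and shrink as it rises", {
  set.seed(64)
  f <- rnorm(30)
  A <- rbind(t1 = f + rnorm(30, 0, 0.2), t2 = f + rnorm(30, 0, 0.2),
             t3 = rnorm(30), t4 = rnorm(30))
  colnames(A) <- paste0("s", 1:30)
  ta <- structure(list(term_ids = rownames(A), module = rep("none", 4),
                       sample_ids = colnames(A), activity = abs(A)),
                  class = "term_activity")
  S <- term_similarity(ta, colnames(A))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(r) {
    igraph::ecount(build_network(S, r_min = r))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # r_min = 1 keeps only perfectly correlated pairs
  expect_equal(counts[5], 0)
  net <- build_network(S, r_min = 0.6)
  expect_true(igraph::are_adjacent(net, "t1", "t2"))
  expect_false(igraph::are_adjacent(net, "t3", "t4"))
})

test_that("two disconnected cliques form exactly two communities", {
  el <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
              c("b1", "b2"), c("b2", "b3"), c("b1", "b3"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], weight = 0.9), directed = FALSE)
  com <- detect_communities(g)
  expect_equal(com$n_communities, 2L)
  expect_length(unique(com$membership[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(com$membership[c("b1", "b2", "b3")]), 1L)
  # disconnected communities have no bridges
  expect_warning(br <- bridge_nodes(g, com), regexp = NA)
  expect_equal(nrow(br), 0L)
  # single edge: no crash, modularity defined
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "x", to = "y", weight = 1), directed = FALSE)
  expect_silent(com1 <- detect_communities(g1))
  expect_true(is.finite(com1$modularity))
})

test_that("the barbell path node carries all inter-community traffic", {
  el <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
              c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
              c("a1", "bridge"), c("bridge", "b1"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               weight = c(rep(0.9, 6), 0.7, 0.7)), directed = FALSE)
  com <- detect_communities(g)
  br <- bridge_nodes(g, com, top_n = 3)
  expect_equal(br$term_id[1], "bridge")
})
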