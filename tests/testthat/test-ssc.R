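# Three tight, well-separated blobs in signature space for deterministic
# clustering behaviour.
blob_matrix <- function(n_per = 8, n_genes = 12, sep = 6, sd = 0.2,
                        seed = 5) {
  set.seed(seed)
  # each blob is elevated on its own gene block, so the clusters differ in
  # profile shape (visible to correlation distance) and in location
  block <- n_genes / 3
  centers <- rbind(c(rep(sep, block), rep(0, 2 * block)),
                   c(rep(0, block), rep(sep, block), rep(0, block)),
                   c(rep(0, 2 * block), rep(sep, block)))
  m <- do.call(cbind, lapply(1:3, function(cl) {
    matrix(rnorm(n_genes * n_per, centers[cl, ], sd), n_genes)
  }))
  dimnames(m) <- list(paste0("g", 1:n_genes), paste0("s", 1:(3 * n_per)))
  attr(m, "truth") <- rep(1:3, each = n_per)
  m
}

std <- function(m) (m - rowMeans(m)) / apply(m, 1, sd)

test_that("well-separated blobs give k = 3 unanimously", {
  m <- blob_matrix()
  ck <- choose_k(std(m), k_range = 2:5, B = 20, seed = 1)
  expect_equal(ck$k, 3)
  expect_true(all(ck$votes == 3))
})

test_that("a single Gaussian blob is not split: the gap vote stays at 2
           and the modal majority is 2", {
  ks <- integer(0); gap_votes <- integer(0)
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(rnorm(12 * 80), 12, 80,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:80)))
    ck <- choose_k(std(m), k_range = 2:5, B = 20, seed = seed)
    ks <- c(ks, ck$k)
    gap_votes <- c(gap_votes, ck$votes[["gap"]])
  }
  # the gap statistic always prefers the bottom of the range on null data
  expect_true(all(gap_votes == 2))
  # silhouette and CH can occasionally coincide on a spurious k, so the
  # guarantee is modal, not per-seed
  expect_equal(as.integer(names(which.max(table(ks)))), 2L)
  expect_gte(mean(ks <= 2), 0.8)
  expect_error(choose_k(matrix(1, 5, 10, dimnames = list(paste0("g", 1:5),
                                                         paste0("s", 1:10)))),
               "identical")
})

test_that("unanimous base partitions give back the same consensus", {
  m <- blob_matrix()
  cons <- consensus_partition(std(m), 3, seed = 2)
  # the three base partitions agree on these blobs, so co-association is 0/1
  expect_true(all(cons$coassociation %in% c(0, 1)))
  expect_equal(mclust::adjustedRandIndex(cons$labels, attr(m, "truth")), 1)
})

test_that("co-association entries live on the 1/3 grid", {
  coh <- small_cohort(41, n_patients = 15, visits_min = 3, visits_max = 4)
  sig <- c(coh$truth$ifn_genes, coh$truth$ne_genes)
  ids <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
  Z <- std(coh$expression[sig, ids])
  cons <- consensus_partition(Z, 3, seed = 1)
  expect_true(all(abs(cons$coassociation * 3 - round(cons$coassociation * 3))
                  < 1e-9))
})

test_that("centroids equal the samples when each forms its own cluster", {
  m <- blob_matrix(n_per = 1, sd = 0.1)
  labels <- setNames(1:3, colnames(m))
  model <- fit_centroids(m, rownames(m), labels)
  Z <- (m - model$gene_means) / model$gene_sds
  expect_equal(unname(model$centroids), unname(t(Z)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two identical samples merged into one cluster -> centroid is that value
  m2 <- cbind(m, s4 = m[, 3])
  model2 <- fit_centroids(m2, rownames(m2), setNames(c(1, 2, 3, 3),
                                                     colnames(m2)))
  Z2 <- (m2 - model2$gene_means) / model2$gene_sds
  expect_equal(unname(model2$centroids[3, ]), unname(Z2[, 3]),
               tolerance = 1e-12)
})

test_that("random labels on random data give near-zero centroids", {
  set.seed(6)
  m <- matrix(rnorm(20 * 120, 7, 1), 20, 120,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:120)))
  labels <- setNames(rep(1:2, each = 60), colnames(m))
  model <- fit_centroids(m, rownames(m), labels)
  expect_lt(max(sqrt(rowSums(model$centroids^2)) / sqrt(20)), 0.2)
})

test_that("correction stops immediately at a fixed point", {
  m <- blob_matrix(n_per = 6, sd = 1e-6)
  labels <- setNames(attr(m, "truth"), colnames(m))
  model <- fit_centroids(m, rownames(m), labels)
  corr <- iterative_correction(model, m)
  expect_equal(corr$n_iterations, 1)
  expect_equal(corr$labels, labels)
})

test_that("correction never increases within-cluster sum of squares", {
  for (seed in 1:3) {
    coh <- small_cohort(seed + 50, n_patients = 20, visits_min = 3,
                        visits_max = 5)
    sig <- c(coh$truth$ifn_genes, coh$truth$ne_genes)
    ids <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
    mat <- coh$expression[, ids]
    truth <- as.integer(factor(coh$truth$subtype_of_sample[ids]))
    # corrupt 10% of the true labels and let the correction recover
    set.seed(seed)
    noisy <- truth
    flip <- sample(length(noisy), ceiling(0.1 * length(noisy)))
    noisy[flip] <- sample(1:3, length(flip), replace = TRUE)
    model <- fit_centroids(mat, sig, setNames(noisy, ids))
    corr <- iterative_correction(model, mat, tol_frac = 0)
    expect_true(all(diff(corr$wcss) <= 1e-8))
    expect_gte(mclust::adjustedRandIndex(corr$labels, truth),
               mclust::adjustedRandIndex(noisy, truth))
  }
})

test_that("classification nails exact centroids and breaks ties low", {
  m <- blob_matrix(n_per = 4, sd = 0.3)
  labels <- setNames(attr(m, "truth"), colnames(m))
  model <- fit_centroids(m, rownames(m), labels)
  # a sample placed exactly at centroid 2 (unstandardized coordinates)
  x2 <- model$centroids[2, ] * model$gene_sds + model$gene_means
  probe <- cbind(p1 = x2)
  asg <- ssc_classify(model, probe)
  expect_equal(asg$cluster, 2L)
  expect_equal(asg$dist_2, 0, tolerance = 1e-12)
  expect_equal(which.max(as.numeric(asg[1, paste0("lik_", 1:3)])), 2L)
  # likelihoods sum to one
  expect_equal(sum(asg[1, paste0("lik_", 1:3)]), 1, tolerance = 1e-12)
  # equidistant probe: lowest index wins, likelihood uniform
  mid <- colMeans(model$centroids) * model$gene_sds + model$gene_means
  asg2 <- ssc_classify(model, cbind(pm = mid))
  expect_equal(asg2$cluster, which.min(abs(
    as.numeric(asg2[1, paste0("dist_", 1:3)]) -
      min(as.numeric(asg2[1, paste0("dist_", 1:3)])))))
})

test_that("classification is deterministic and order-independent", {
  coh <- small_cohort(42, n_patients = 12, visits_min = 3, visits_max = 4)
  sig <- c(coh$truth$ifn_genes, coh$truth$ne_genes)
  ids <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
  mat <- coh$expression[, ids]
  labels <- setNames(as.integer(factor(coh$truth$subtype_of_sample[ids])), ids)
  model <- fit_centroids(mat, sig, labels)
  a1 <- ssc_classify(model, mat)
  a2 <- ssc_classify(model, mat[, rev(ids)])
  a2 <- a2[match(a1$sample_id, a2$sample_id), ]
  rownames(a2) <- NULL
  expect_equal(a1, a2)
  expect_error(ssc_classify(model, mat[-(1:3), ]), "missing")
})

test_that("a model survives the JSON round trip with identical assignments", {
  coh <- small_cohort(43, n_patients = 12, visits_min = 3, visits_max = 4)
  sig <- c(coh$truth$ifn_genes, coh$truth$ne_genes)
  ids <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
  mat <- coh$expression[, ids]
  labels <- setNames(as.integer(factor(coh$truth$subtype_of_sample[ids])), ids)
  model <- fit_centroids(mat, sig, labels)
  f <- withr::local_tempfile(fileext = ".json")
  save_ssc(model, f)
  model2 <- load_ssc(f)
  expect_identical(ssc_classify(model, mat), ssc_classify(model2, mat))
})

test_that("Kruskal-Wallis output matches a brute-force rank computation", {
  labels <- setNames(rep(c("a", "b", "c"), each = 3), paste0("s", 1:9))
  clin <- data.frame(
    patient_id = paste0("P", 1:9), sample_id = paste0("s", 1:9),
    visit_index = 0L, time_days = 0,
    sledai = c(1, 2, 3, 7, 8, 9, 14, 15, 16), state = "SLE",
    age_group = "adult", sex = "female", race = "white", drug_cs = FALSE,
    drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE, cohort = "A",
    stringsAsFactors = FALSE)
  res <- sledai_by_subtype(labels, clin, trim = FALSE)
  # brute force: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 (no ties)
  r <- rank(clin$sledai)
  N <- 9
  H <- 12 / (N * (N + 1)) *
    sum(vapply(split(r, rep(1:3, each = 3)),
               function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2,
               numeric(1)))
  expect_equal(res$kw_stat, H, tolerance = 1e-9)
  expect_equal(nrow(res$pairwise), 3L)
})

test_that("the Tukey trim removes extreme SLEDAI values", {
  labels <- setNames(rep(c("a", "b"), each = 10), paste0("s", 1:20))
  clin <- data.frame(
    patient_id = paste0("P", 1:20), sample_id = paste0("s", 1:20),
    visit_index = 0L, time_days = 0,
    sledai = c(rep(c(4, 5, 6, 5, 4), 2), rep(c(7, 8, 9, 8, 7), 2)),
    state = "SLE", age_group = "adult", sex = "female", race = "white",
    drug_cs = FALSE, drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE,
    cohort = "A", stringsAsFactors = FALSE)
  clin$sledai[1] <- 80    # far outside the fences
  res <- sledai_by_subtype(labels, clin, trim = TRUE)
  expect_equal(res$n_trimmed, 1L)
  expect_equal(sledai_by_subtype(labels, clin, trim = FALSE)$n_trimmed, 0L)
})
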