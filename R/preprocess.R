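#' Exclude patients unsuitable for the longitudinal screen
#'
#' Removes SLE patients with (a) any missing SLEDAI or required field,
#' (b) drug exposure flags that change across visits, or (c) a SLEDAI that
#' stays exactly constant over two or more visits (no disease-activity
#' variation to correlate against). Healthy controls are always kept, and
#' single-visit patients with complete data are kept (no variance is
#' defined for one visit).
#'
#' @param clinical Clinical table.
#' @return A list with `clinical` (the retained rows) and `exclusions`
#'   (a `data.frame` of `patient_id`, `reason`).
#' @export
exclude_patients <- function(clinical) {
  req <- c("patient_id", "sample_id", "time_days", "sledai", "state",
           "age_group", "sex", "race")
  excl <- list()
  for (p in unique(clinical$patient_id[clinical$state == "SLE"])) {
    rows <- clinical[clinical$patient_id == p, , drop = FALSE]
    if (anyNA(rows[, req]) ||
        anyNA(rows[, c("drug_cs", "drug_hc", "drug_is", "drug_ifnk")])) {
      excl[[p]] <- "missing data"
      next
    }
    changed <- vapply(c("drug_cs", "drug_hc", "drug_is", "drug_ifnk"),
                      function(d) length(unique(rows[[d]])) > 1, logical(1))
    if (any(changed)) {
      excl[[p]] <- "drug change"
      next
    }
    if (nrow(rows) >= 2 && stats::var(rows$sledai) == 0) {
      excl[[p]] <- "stable SLEDAI"
    }
  }
  report <- data.frame(patient_id = names(excl),
                       reason = unlist(excl, use.names = FALSE),
                       stringsAsFactors = FALSE)
  keep <- !(clinical$patient_id %in% report$patient_id)
  list(clinical = clinical[keep, , drop = FALSE], exclusions = report)
}

#' Quantile-normalize an expression matrix
#'
#' Standard quantile normalization: every sample (column) is mapped onto the
#' common reference distribution given by the row means of the
#' column-sorted matrix, preserving within-column rank order. Tied entries
#' within a column receive the mean of the reference values over their rank
#' span.
#'
#' @param mat Expression matrix (genes x samples), >= 2 samples.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2) stop_("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(mat, 2, sort))
  cs <- cumsum(ref)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    rmin <- rank(x, ties.method = "min")
    cnt <- stats::ave(x, x, FUN = length)
    hi <- rmin + cnt - 1
    out[, j] <- (cs[hi] - c(0, cs)[rmin]) / cnt
  }
  out
}

#' Remove genes with low variability across samples
#'
#' Drops genes whose sample standard deviation (n - 1 denominator) falls
#' below `sd_min`; near-constant transcripts carry no usable signal on the
#' log2 intensity scale.
#'
#' @param mat Expression matrix.
#' @param sd_min Minimum SD to keep a gene (default 0.1).
#' @return The row-filtered matrix.
#' @export
filter_low_variance <- function(mat, sd_min = 0.1) {
  sds <- apply(mat, 1, stats::sd)
  keep <- sds >= sd_min
  if (!any(keep)) {
    stop_("all genes removed at sd_min = %g; lower the threshold", sd_min)
  }
  mat[keep, , drop = FALSE]
}

#' Merge duplicated gene rows by mean expression
#'
#' Collapses rows sharing a gene symbol to their per-sample arithmetic
#' mean, preserving first-occurrence row order.
#'
#' @param mat Expression matrix (possibly with duplicated rownames).
#' @return Matrix with one row per gene symbol.
#' @export
collapse_duplicates <- function(mat) {
  g <- rownames(mat)
  if (!anyDuplicated(g)) return(mat)
  first <- !duplicated(g)
  sums <- rowsum(mat, group = g, reorder = FALSE)
  n <- as.vector(table(factor(g, levels = rownames(sums))))
  out <- sums / n
  out[match(g[first], rownames(out)), , drop = FALSE]
}

#' Split a cohort into discovery and test sets at the patient level
#'
#' All visits of a patient stay together. The split is stratified by
#' `(cohort, state)` so both data sources and the healthy controls are
#' balanced across the two sets, and is deterministic given `seed`. The
#' discovery set takes `ratio[1] / sum(ratio)` of the patients in each
#' stratum (rounded).
#'
#' @param clinical Clinical table.
#' @param ratio Two integers, discovery : test (default `c(2, 1)`).
#' @param seed Integer seed.
#' @return A list with character vectors `discovery_patients` and
#'   `test_patients`.
#' @export
split_cohort <- function(clinical, ratio = c(2, 1), seed = 1L) {
  n_sle <- length(unique(clinical$patient_id[clinical$state == "SLE"]))
  if (n_sle < 3) stop_("need >= 3 SLE patients to split (got %d)", n_sle)
  frac <- ratio[1] / sum(ratio)
  pt <- unique(clinical[, c("patient_id", "cohort", "state")])
  withr::with_seed(seed, {
    disc <- character(0)
    for (s in split(pt$patient_id, paste(pt$cohort, pt$state))) {
      n_d <- round(frac * length(s))
      disc <- c(disc, sample(s, n_d))
    }
  })
  list(discovery_patients = sort(disc),
       test_patients = sort(setdiff(pt$patient_id, disc)))
}

#' Run the full preprocessing pipeline
#'
#' Exclusion, quantile normalization, SD filtering, duplicate-gene merging
#' and the 2:1 discovery/test split, in that order (normalizing before the
#' SD filter keeps the threshold on a common scale). The filter/normalize
#' order can be swapped via `sd_filter_first`.
#'
#' @param mat Expression matrix.
#' @param clinical Clinical table.
#' @param sd_min SD threshold for [filter_low_variance()].
#' @param split_seed Seed for [split_cohort()].
#' @param sd_filter_first Apply the SD filter before normalization.
#' @return A list: `expression`, `clinical`, `exclusions`, `split`.
#' @export
preprocess_pipeline <- function(mat, clinical, sd_min = 0.1, split_seed = 1L,
                                sd_filter_first = FALSE) {
  ex <- exclude_patients(clinical)
  clin <- ex$clinical
  mat <- mat[, colnames(mat) %in% clin$sample_id, drop = FALSE]
  if (sd_filter_first) mat <- filter_low_variance(mat, sd_min)
  mat <- quantile_normalize(mat)
  if (!sd_filter_first) mat <- filter_low_variance(mat, sd_min)
  mat <- collapse_duplicates(mat)
  list(expression = mat, clinical = clin, exclusions = ex$exclusions,
       split = split_cohort(clin, seed = split_seed))
}
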