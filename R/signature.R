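#' ANOVA screen for differential expression between disease states
#'
#' Per-gene one-way ANOVA between the `SLE` and `healthy` groups (samples
#' treated as independent), with Benjamini-Hochberg adjustment. Genes with
#' `q_value < q_max` are flagged as differentially expressed (DEGs).
#'
#' @param mat Expression matrix (genes x samples).
#' @param clinical Clinical table covering the matrix samples.
#' @param q_max FDR threshold for the DEG flag (default 0.05).
#' @return `data.frame` with `gene`, `f_stat`, `p_value`, `q_value`, `deg`.
#' @export
anova_screen <- function(mat, clinical, q_max = 0.05) {
  state <- clinical$state[match(colnames(mat), clinical$sample_id)]
  if (anyNA(state)) stop_("samples missing from clinical table")
  if (length(unique(state)) < 2) {
    stop_("need both SLE and healthy samples for the ANOVA screen")
  }
  res <- row_anova(mat, state)
  q <- stats::p.adjust(res$p, method = "BH")
  data.frame(gene = rownames(mat), f_stat = res$f, p_value = res$p,
             q_value = q, deg = q < q_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Patient weights for the disease-activity correlation score
#'
#' Longitudinal cohorts are unbalanced: patients differ in visit counts and
#' record completeness. Patients with at least `min_visits` complete visits
#' and non-zero SLEDAI variance receive a weight proportional to their
#' number of visits, normalized to sum 1; all others get weight 0 and are
#' excluded from scoring. Proportional-to-information weighting keeps the
#' weighted score in \[0, 1\].
#'
#' @param clinical Clinical table.
#' @param min_visits Minimum visits for a defined correlation (default 3).
#' @return Named numeric vector of weights summing to 1 over eligible
#'   patients (ineligible patients are present with weight 0).
#' @export
patient_weights <- function(clinical, min_visits = 3) {
  sle <- clinical[clinical$state == "SLE", , drop = FALSE]
  pats <- unique(sle$patient_id)
  w <- stats::setNames(numeric(length(pats)), pats)
  for (p in pats) {
    s <- sle$sledai[sle$patient_id == p]
    if (length(s) >= min_visits && !anyNA(s) && stats::var(s) > 0) {
      w[p] <- length(s)
    }
  }
  if (all(w == 0)) stop_("no patient has enough varying SLEDAI visits to score")
  w / sum(w)
}

# Core scorer: per-patient correlation of each gene with SLEDAI and the
# weighted |r| sum. Shared by activity_score and the permutation loop.
#' @noRd
score_genes <- function(mat, patient_samples, sledai, weights,
                        method = "spearman") {
  active <- names(weights)[weights > 0]
  r <- matrix(0, nrow(mat), length(active),
              dimnames = list(rownames(mat), active))
  for (p in active) {
    ids <- patient_samples[[p]]
    x <- mat[, ids, drop = FALSE]
    s <- sledai[ids]
    if (method == "spearman") {
      x <- row_ranks(x)
      s <- rank(s)
    }
    r[, p] <- row_cor(x, s)
  }
  score <- as.vector(abs(r) %*% weights[active])
  names(score) <- rownames(mat)
  list(per_patient_r = r, score = score)
}

#' @noRd
patient_sample_map <- function(clinical, weights) {
  sle <- clinical[clinical$state == "SLE", , drop = FALSE]
  split(sle$sample_id, sle$patient_id)[names(weights)[weights > 0]]
}

#' Disease-activity correlation score
#'
#' For each gene, the correlation between its expression and the SLEDAI
#' score is computed across each patient's visits; the gene's score is the
#' patient-weighted sum of absolute correlations,
#' `score(g) = sum_p w_p |r_p(g)|`, which lies in \[0, 1\]. Spearman (the
#' default; SLEDAI is ordinal) or Pearson correlation. Genes that are flat
#' within a patient contribute `r_p = 0` for that patient.
#'
#' @param mat Expression matrix.
#' @param clinical Clinical table.
#' @param genes Genes to score (must be rows of `mat`).
#' @param weights Output of [patient_weights()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list: `per_patient_r` (gene x patient matrix) and `score`
#'   (named numeric).
#' @export
activity_score <- function(mat, clinical, genes, weights,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  missing_g <- setdiff(genes, rownames(mat))
  if (length(missing_g)) {
    stop_("gene(s) absent from matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  }
  sledai <- stats::setNames(clinical$sledai, clinical$sample_id)
  ps <- patient_sample_map(clinical, weights)
  score_genes(mat[genes, , drop = FALSE], ps, sledai, weights, method)
}

#' Permutation calibration of the activity score
#'
#' Each of `n_perm` permutations independently shuffles the gene (row)
#' labels and the sample (column) labels of the expression matrix, breaking
#' the gene-sample linkage, and recomputes the scores. The per-gene
#' permutation p-value uses the add-one estimator
#' `perm_p(g) = (1 + #\{b : score_b(g) >= score_obs(g)\}) / (n_perm + 1)`.
#'
#' @inheritParams activity_score
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `perm_p` (named numeric), `observed` (scores), and
#'   `null_mean_score` (mean permuted score per replicate, used by
#'   diagnostics).
#' @export
permutation_calibration <- function(mat, clinical, genes, weights,
                                    n_perm = 1000, seed = 1L,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (n_perm < 1) stop_("n_perm must be >= 1")
  obs <- activity_score(mat, clinical, genes, weights, method)$score
  sledai <- stats::setNames(clinical$sledai, clinical$sample_id)
  ps <- patient_sample_map(clinical, weights)
  ge <- stats::setNames(numeric(length(genes)), genes)
  null_mean <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- mat[sample.int(nrow(mat)), sample.int(ncol(mat)), drop = FALSE]
      dimnames(pm) <- dimnames(mat)
      sb <- score_genes(pm[genes, , drop = FALSE], ps, sledai, weights,
                        method)$score
      ge <- ge + (sb >= obs)
      null_mean[b] <- mean(sb)
    }
  })
  list(perm_p = (1 + ge) / (n_perm + 1), observed = obs,
       null_mean_score = null_mean)
}

#' Compare DEG scores against random gene sets
#'
#' Draws `n_random` random gene sets of the same size as the DEG set from
#' the non-DEG genes, and compares mean activity scores. The empirical
#' p-value is `(1 + #\{draws with mean_random >= mean_DEG\}) / (n_random + 1)`.
#'
#' @param mat Expression matrix.
#' @param clinical Clinical table.
#' @param deg_genes Character vector of DEG gene ids.
#' @param weights Output of [patient_weights()].
#' @param n_random Number of random draws (default 1000).
#' @param seed Integer seed.
#' @param method Correlation type.
#' @return A list: `p`, `mean_deg`, `mean_random` (vector of draw means).
#' @export
random_geneset_comparison <- function(mat, clinical, deg_genes, weights,
                                      n_random = 1000, seed = 1L,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pool <- setdiff(rownames(mat), deg_genes)
  if (length(pool) < length(deg_genes)) {
    stop_("only %d non-DEG genes available for sets of size %d",
          length(pool), length(deg_genes))
  }
  all_scores <- activity_score(mat, clinical, rownames(mat), weights,
                               method)$score
  mean_deg <- mean(all_scores[deg_genes])
  withr::with_seed(seed, {
    mean_rand <- vapply(seq_len(n_random), function(b) {
      mean(all_scores[sample(pool, length(deg_genes))])
    }, numeric(1))
  })
  list(p = (1 + sum(mean_rand >= mean_deg)) / (n_random + 1),
       mean_deg = mean_deg, mean_random = mean_rand)
}

#' Select the disease-activity gene signature
#'
#' Keeps genes that are both differentially expressed (`q_value < q_max`)
#' and strongly activity-correlated (`score > score_min`, strict), sorted
#' by descending score.
#'
#' @param result `data.frame` with at least `gene`, `q_value`, `score`
#'   columns (see [signature_screen()]).
#' @param q_max FDR threshold (default 0.05).
#' @param score_min Score threshold (default 0.6, strict inequality).
#' @return Character vector of selected genes (may be empty, with warning).
#' @export
select_signature <- function(result, q_max = 0.05, score_min = 0.6) {
  sel <- result$q_value < q_max & result$score > score_min
  sel[is.na(sel)] <- FALSE
  genes <- result$gene[sel][order(result$score[sel], decreasing = TRUE)]
  if (!length(genes)) warn_("no genes pass q < %g and score > %g", q_max, score_min)
  genes
}

#' Run the full signature screen
#'
#' Orchestrates [anova_screen()], [patient_weights()], [activity_score()]
#' on the DEGs, [permutation_calibration()], and [select_signature()].
#'
#' @inheritParams anova_screen
#' @param score_min Score threshold for selection.
#' @param n_perm Permutations (0 skips calibration).
#' @param min_visits Minimum visits per scored patient.
#' @param seed Integer seed.
#' @param method Correlation type.
#' @return A list: `result` (per-gene table over DEGs), `signature`
#'   (selected genes), `weights`.
#' @export
signature_screen <- function(mat, clinical, q_max = 0.05, score_min = 0.6,
                             n_perm = 1000, min_visits = 3, seed = 1L,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  screen <- anova_screen(mat, clinical, q_max)
  degs <- screen$gene[screen$deg]
  if (!length(degs)) {
    warn_("no DEGs at q < %g; empty signature", q_max)
    return(list(result = cbind(screen, score = NA_real_, perm_p = NA_real_,
                               selected = FALSE)[0, ],
                signature = character(0), weights = NULL))
  }
  w <- patient_weights(clinical, min_visits)
  sc <- activity_score(mat, clinical, degs, w, method)
  res <- screen[screen$deg, , drop = FALSE]
  res$score <- sc$score[res$gene]
  if (n_perm > 0) {
    pc <- permutation_calibration(mat, clinical, degs, w, n_perm, seed, method)
    res$perm_p <- pc$perm_p[res$gene]
  } else {
    res$perm_p <- NA_real_
  }
  sig <- select_signature(res, q_max, score_min)
  res$selected <- res$gene %in% sig
  res <- res[order(res$score, decreasing = TRUE), ]
  rownames(res) <- NULL
  list(result = res, signature = sig, weights = w)
}
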