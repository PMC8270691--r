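# Consensus clustering over the signature space and the nearest-centroid
# single-sample classifier built from it.

#' @noRd
standardize_with <- function(mat, genes, means, sds) {
  missing_g <- setdiff(genes, rownames(mat))
  if (length(missing_g)) {
    stop_("signature gene(s) missing from matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  }
  (mat[genes, , drop = FALSE] - means) / sds
}

# Euclidean distances (samples x k) in standardized space.
#' @noRd
centroid_distances <- function(Z, centroids) {
  X <- t(Z)
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") -
    2 * X %*% t(centroids)
  sqrt(pmax(d2, 0))
}

# Calinski-Harabasz index for an arbitrary partition (between-cluster over
# within-cluster dispersion, df-scaled). No installed package exposes this
# for a given labelling, so it is computed directly.
#' @noRd
ch_index <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  gm <- colMeans(X)
  ssw <- 0; ssb <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    ci <- colMeans(Xi)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
    ssb <- ssb + nrow(Xi) * sum((ci - gm)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Choose the number of subtypes by majority vote of three indices
#'
#' Three independent k-selection criteria each cast a vote over `k_range`:
#' average silhouette width on PAM (k-medoids) partitions, the
#' Calinski-Harabasz index on the same partitions, and the gap statistic on
#' k-means partitions (`B` reference draws, first-SE-max rule). The
#' returned k is the majority vote, ties broken toward smaller k.
#'
#' @param Z Standardized signature matrix (genes x samples).
#' @param k_range Candidate cluster counts (default 2:6).
#' @param B Reference draws for the gap statistic (default 50).
#' @param seed Integer seed (gap statistic and k-means restarts).
#' @return A list: `k` (the vote winner) and `votes` (named integer vector
#'   per criterion).
#' @export
choose_k <- function(Z, k_range = 2:6, B = 50, seed = 1L) {
  X <- t(Z)
  if (nrow(X) < max(k_range) + 1) stop_("need more samples than max(k_range)")
  if (all(apply(X, 2, stats::sd) < 1e-12)) {
    stop_("all samples identical; no cluster structure to select k from")
  }
  withr::with_seed(seed, {
    sil <- ch <- stats::setNames(numeric(length(k_range)), k_range)
    for (i in seq_along(k_range)) {
      pm <- cluster::pam(X, k_range[i])
      sil[i] <- pm$silinfo$avg.width
      ch[i] <- ch_index(X, pm$clustering)
    }
    gap <- cluster::clusGap(
      X, FUN = function(x, k) list(cluster = stats::kmeans(x, k, nstart = 5,
                                                           iter.max = 30)$cluster),
      K.max = max(k_range), B = B, verbose = FALSE)
    k_gap <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                            method = "firstSEmax")
  })
  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             gap = max(min(k_range), min(k_gap, max(k_range))))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = votes)
}

#' Consensus partition from three base clusterings
#'
#' Combines k-medoids with Euclidean distance, k-medoids with correlation
#' distance (1 - r), and Ward agglomerative clustering cut at k, via a
#' sample x sample co-association matrix (the fraction of base partitions
#' co-clustering each pair). Final labels come from average-linkage
#' hierarchical clustering of 1 - co-association, cut at k.
#'
#' @param Z Standardized signature matrix (genes x samples).
#' @param k Number of clusters.
#' @param seed Integer seed (medoid initialization).
#' @return A list: `labels` (named integer vector), `coassociation`
#'   (sample x sample matrix), `base` (matrix of the three base labelings).
#' @export
consensus_partition <- function(Z, k, seed = 1L) {
  X <- t(Z)
  withr::with_seed(seed, {
    p1 <- cluster::pam(X, k, cluster.only = TRUE)
    p2 <- cluster::pam(stats::as.dist(1 - stats::cor(Z)), k, diss = TRUE,
                       cluster.only = TRUE)
    p3 <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k)
  })
  base <- cbind(euclid_medoid = p1, cor_medoid = p2, ward = p3)
  C <- (outer(p1, p1, "==") + outer(p2, p2, "==") + outer(p3, p3, "==")) / 3
  dimnames(C) <- list(rownames(X), rownames(X))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(hc, k)
  names(labels) <- rownames(X)
  list(labels = labels, coassociation = C, base = base)
}

#' Fit subtype centroids from a labelled training set
#'
#' Standardizes the signature genes from the training samples (the
#' standardization parameters are stored and reused at classification
#' time) and sets each centroid to the per-gene mean of its cluster's
#' standardized expression -- the subtype "feature values".
#'
#' @param mat Expression matrix containing the training samples.
#' @param signature_genes Ordered signature gene list.
#' @param labels Named integer cluster labels (1..k) for the columns of
#'   `mat` to train on.
#' @return An object of class `ssc_model`.
#' @export
fit_centroids <- function(mat, signature_genes, labels) {
  ids <- names(labels)
  if (is.null(ids) || !all(ids %in% colnames(mat))) {
    stop_("labels must be named by training sample ids present in mat")
  }
  sub <- mat[, ids, drop = FALSE]
  missing_g <- setdiff(signature_genes, rownames(sub))
  if (length(missing_g)) {
    stop_("signature gene(s) missing from matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  }
  means <- rowMeans(sub[signature_genes, , drop = FALSE])
  sds <- apply(sub[signature_genes, , drop = FALSE], 1, stats::sd)
  if (any(sds <= 0)) {
    stop_("zero-variance signature gene(s) in training data: %s",
          paste(utils::head(signature_genes[sds <= 0], 5), collapse = ", "))
  }
  Z <- standardize_with(sub, signature_genes, means, sds)
  k <- max(labels)
  if (!setequal(unique(labels), seq_len(k))) stop_("empty cluster in labels")
  cent <- t(vapply(seq_len(k), function(cl) {
    rowMeans(Z[, labels == cl, drop = FALSE])
  }, numeric(length(signature_genes))))
  rownames(cent) <- paste0("subtype_", seq_len(k))
  structure(list(k = k, signature_genes = signature_genes,
                 gene_means = means, gene_sds = sds, centroids = cent,
                 subtype_names = NULL, training_labels = labels),
            class = "ssc_model")
}

#' Iteratively correct subtype labels to convergence
#'
#' Alternates nearest-centroid reassignment (Euclidean distance in the
#' standardized signature space, ties to the lowest cluster index) with
#' centroid recomputation until fewer than `tol_frac` of the labels change
#' or `max_iter` iterations. A centroid that loses all members keeps its
#' previous value (with a warning). The within-cluster sum of squared
#' distances is non-increasing across iterations by construction and its
#' trace is returned.
#'
#' @param model An `ssc_model` from [fit_centroids()].
#' @param mat Expression matrix with the training samples.
#' @param tol_frac Convergence threshold on the fraction of changed labels
#'   (default 0.01).
#' @param max_iter Iteration cap (default 50).
#' @return A list: `model` (updated centroids and training labels),
#'   `labels`, `n_iterations`, `wcss` (trace, one value per iteration).
#' @export
iterative_correction <- function(model, mat, tol_frac = 0.01, max_iter = 50) {
  ids <- names(model$training_labels)
  Z <- standardize_with(mat[, ids, drop = FALSE], model$signature_genes,
                        model$gene_means, model$gene_sds)
  cent <- model$centroids
  labels <- model$training_labels
  wcss <- numeric(0)
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    d <- centroid_distances(Z, cent)
    new_labels <- apply(d, 1, which.min)   # which.min takes the lowest index on ties
    names(new_labels) <- ids
    wcss <- c(wcss, sum(d[cbind(seq_along(new_labels), new_labels)]^2))
    changed <- mean(new_labels != labels)
    labels <- new_labels
    n_iter <- it
    for (cl in seq_len(model$k)) {
      if (any(labels == cl)) {
        cent[cl, ] <- rowMeans(Z[, labels == cl, drop = FALSE])
      } else {
        warn_("cluster %d lost all members at iteration %d; keeping previous centroid",
              cl, it)
      }
    }
    if (changed < tol_frac) break
  }
  model$centroids <- cent
  model$training_labels <- labels
  list(model = model, labels = labels, n_iterations = n_iter, wcss = wcss)
}

#' Classify samples with the single-sample subtype classifier
#'
#' Standardizes each sample's signature genes with the training means/SDs,
#' computes Euclidean distances to the stored centroids, assigns the
#' nearest (ties to the lowest cluster index), and converts distances to a
#' likelihood via `softmax(-distance)`. Each sample is classified
#' independently, so one sample at a time works.
#'
#' @param model An `ssc_model`.
#' @param mat Expression matrix of samples to classify (genes x samples).
#' @return `data.frame` with `sample_id`, `cluster`, `subtype` (named if
#'   the model has been through [name_subtypes()]), `dist_*` and `lik_*`
#'   columns.
#' @export
ssc_classify <- function(model, mat) {
  Z <- standardize_with(mat, model$signature_genes,
                        model$gene_means, model$gene_sds)
  d <- centroid_distances(Z, model$centroids)
  lab <- apply(d, 1, which.min)
  el <- exp(-(d - apply(d, 1, min)))     # stabilized softmax(-distance)
  lik <- el / rowSums(el)
  subtype <- if (!is.null(model$subtype_names)) {
    unname(model$subtype_names[lab])
  } else {
    paste0("subtype_", lab)
  }
  out <- data.frame(sample_id = colnames(mat), cluster = lab,
                    subtype = subtype, stringsAsFactors = FALSE)
  colnames(d) <- paste0("dist_", seq_len(model$k))
  colnames(lik) <- paste0("lik_", seq_len(model$k))
  out <- cbind(out, d, lik)
  rownames(out) <- NULL
  out
}

#' Name clusters by their IFN / NE module activity pattern
#'
#' A cluster whose mean IFN-module and NE-module (bacterial + fungal
#' terms) activities both exceed the healthy baseline (mean + 2 SD over
#' healthy samples) is `mixed`; IFN only is `IFN-high`; NE only is
#' `NE-high`. An unresolvable pattern (no elevated module, or two clusters
#' mapping to the same name) is an error: the model is not interpretable
#' under this naming scheme.
#'
#' @param model An `ssc_model` with training labels.
#' @param term_activity A `term_activity` object ([ged_activity()])
#'   covering the training and healthy samples.
#' @param clinical Clinical table (identifies healthy samples).
#' @return The model with `subtype_names` set.
#' @export
name_subtypes <- function(model, term_activity, clinical) {
  mod <- term_activity$module
  agg <- function(which_mod, ids) {
    rows <- mod %in% which_mod
    if (!any(rows)) stop_("no terms for module(s) %s", paste(which_mod, collapse = "/"))
    colMeans(term_activity$activity[rows, ids, drop = FALSE])
  }
  healthy_ids <- intersect(
    clinical$sample_id[clinical$state == "healthy"], term_activity$sample_ids)
  if (length(healthy_ids) < 2) stop_("need >= 2 healthy samples with activity")
  names_out <- character(model$k)
  for (cl in seq_len(model$k)) {
    ids <- intersect(names(model$training_labels)[model$training_labels == cl],
                     term_activity$sample_ids)
    if (!length(ids)) stop_("cluster %d has no samples with term activity", cl)
    high <- vapply(list(IFN = "IFN", NE = c("bacterial", "fungal")),
                   function(m) {
                     h <- agg(m, healthy_ids)
                     mean(agg(m, ids)) > mean(h) + 2 * stats::sd(h)
                   }, logical(1))
    names_out[cl] <- if (high[["IFN"]] && high[["NE"]]) "mixed"
      else if (high[["IFN"]]) "IFN-high"
      else if (high[["NE"]]) "NE-high"
      else stop_("cluster %d shows no elevated module; cannot name subtypes", cl)
  }
  if (anyDuplicated(names_out)) {
    stop_("two clusters map to the same subtype name (%s); model not interpretable",
          paste(names_out, collapse = ", "))
  }
  model$subtype_names <- stats::setNames(names_out, seq_len(model$k))
  model
}

#' Compare SLEDAI across subtypes
#'
#' Kruskal-Wallis test of SLEDAI across subtype labels, with pairwise
#' Wilcoxon rank-sum tests (BH-adjusted). SLEDAI outliers can first be
#' trimmed with Tukey fences (values outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] over all SLE samples).
#'
#' @param labels Named vector (by sample id) of subtype labels.
#' @param clinical Clinical table.
#' @param trim Apply the Tukey-fence trim (default TRUE).
#' @return A list: `kw_stat`, `kw_p`, `pairwise` (`data.frame` with
#'   group pair, n, W, p, q), `n_trimmed`.
#' @export
sledai_by_subtype <- function(labels, clinical, trim = TRUE) {
  sl <- clinical$sledai[match(names(labels), clinical$sample_id)]
  st <- clinical$state[match(names(labels), clinical$sample_id)]
  keep <- st == "SLE" & !is.na(sl)
  sl <- sl[keep]; grp <- as.character(labels[keep])
  n_trim <- 0L
  if (trim) {
    q <- stats::quantile(sl, c(0.25, 0.75))
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    inl <- sl >= fence[1] & sl <= fence[2]
    n_trim <- sum(!inl)
    sl <- sl[inl]; grp <- grp[inl]
  }
  tab <- table(grp)
  if (sum(tab >= 2) < 2) stop_("need >= 2 subtypes with >= 2 samples")
  kw <- stats::kruskal.test(sl, factor(grp))
  prs <- utils::combn(names(tab), 2)
  pw <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                   n1 = as.integer(tab[prs[1, ]]), n2 = as.integer(tab[prs[2, ]]),
                   statistic = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    if (pw$n1[i] < 2 || pw$n2[i] < 2) {
      warn_("pairwise test %s vs %s skipped (<2 samples)", prs[1, i], prs[2, i])
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(sl[grp == prs[1, i]],
                                              sl[grp == prs[2, i]]))
    pw$statistic[i] <- wt$statistic
    pw$p_value[i] <- wt$p.value
  }
  pw$q_value <- stats::p.adjust(pw$p_value, "BH")
  list(kw_stat = unname(kw$statistic), kw_p = kw$p.value, pairwise = pw,
       n_trimmed = n_trim)
}

#' Persist an SSC model to JSON
#' @param model An `ssc_model`.
#' @param path Output path.
#' @export
save_ssc <- function(model, path) {
  # explicit schema: parallel arrays aligned to signature_genes / samples
  # (plain JSON arrays survive the round trip with full double precision)
  obj <- list(
    k = model$k,
    signature_genes = model$signature_genes,
    gene_means = unname(model$gene_means),
    gene_sds = unname(model$gene_sds),
    centroids = unname(model$centroids),
    subtype_names = if (is.null(model$subtype_names)) NULL else
      unname(model$subtype_names),
    training_samples = names(model$training_labels),
    training_labels = unname(model$training_labels)
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load an SSC model from JSON
#' @param path Path written by [save_ssc()].
#' @return An `ssc_model` giving identical assignments to the saved one.
#' @export
load_ssc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(as.numeric(obj$centroids), nrow = obj$k)
  dimnames(cent) <- list(paste0("subtype_", seq_len(obj$k)), NULL)
  structure(list(
    k = as.integer(obj$k),
    signature_genes = obj$signature_genes,
    gene_means = stats::setNames(obj$gene_means, obj$signature_genes),
    gene_sds = stats::setNames(obj$gene_sds, obj$signature_genes),
    centroids = cent,
    subtype_names = if (length(obj$subtype_names)) {
      stats::setNames(obj$subtype_names, seq_len(obj$k))
    } else NULL,
    training_labels = if (length(obj$training_labels)) {
      stats::setNames(as.integer(obj$training_labels), obj$training_samples)
    } else NULL
  ), class = "ssc_model")
}

#' Train the single-sample subtype classifier end to end
#'
#' [choose_k()] (unless `k` is given), [consensus_partition()],
#' [fit_centroids()] and [iterative_correction()], on the SLE samples of
#' the supplied matrix restricted to the signature genes.
#'
#' @param mat Expression matrix of training samples.
#' @param signature_genes Signature gene list.
#' @param k Number of subtypes; `NULL` to select by [choose_k()].
#' @param k_range Candidate range when selecting k.
#' @param seed Integer seed.
#' @return A list: `model`, `labels`, `consensus`, `k_votes`,
#'   `n_iterations`, `wcss`.
#' @export
train_ssc <- function(mat, signature_genes, k = NULL, k_range = 2:6,
                      seed = 1L) {
  means <- rowMeans(mat[signature_genes, , drop = FALSE])
  sds <- apply(mat[signature_genes, , drop = FALSE], 1, stats::sd)
  if (any(sds <= 0)) stop_("zero-variance signature gene in training data")
  Z <- standardize_with(mat, signature_genes, means, sds)
  votes <- NULL
  if (is.null(k)) {
    ck <- choose_k(Z, k_range, seed = seed)
    k <- ck$k
    votes <- ck$votes
  }
  cons <- consensus_partition(Z, k, seed)
  model <- fit_centroids(mat, signature_genes, cons$labels)
  corr <- iterative_correction(model, mat)
  list(model = corr$model, labels = corr$labels, consensus = cons,
       k_votes = votes, n_iterations = corr$n_iterations, wcss = corr$wcss)
}
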