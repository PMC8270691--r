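# Gene expression deviation (GED) term activity, signature enrichment,
# per-subtype dysregulation profiles, and the term-activity co-expression
# network.

#' Gene expression deviation (GED) term activity
#'
#' Measures how far each sample's term genes deviate from a healthy
#' reference: genes are z-scored against the healthy mean and SD,
#' `z_gs = (x_gs - mean_healthy_g) / sd_healthy_g`, and a term's activity
#' in a sample is the mean absolute z over the term's genes. A healthy
#' sample drawn from the reference distribution therefore has expected
#' activity `E|Z| = sqrt(2/pi) ~ 0.798` under Gaussian noise. When scoring
#' a healthy sample itself the reference is computed leave-one-out, to
#' avoid the self-reference bias of a plug-in estimate.
#'
#' Genes with zero healthy variance are dropped from all terms (with a
#' warning); terms left with fewer than 3 mapped genes are dropped (with a
#' warning).
#'
#' @param mat Expression matrix.
#' @param clinical Clinical table (identifies healthy samples; >= 2
#'   required, >= 3 for the leave-one-out reference).
#' @param genesets A `geneset_collection`.
#' @param loo_healthy Use the leave-one-out reference for healthy samples
#'   (default TRUE).
#' @param signed Use the signed mean z instead of mean |z| (default FALSE).
#' @return An object of class `term_activity`: list with `term_ids`,
#'   `module`, `sample_ids`, `activity` (term x sample matrix).
#' @export
ged_activity <- function(mat, clinical, genesets, loo_healthy = TRUE,
                         signed = FALSE) {
  healthy_ids <- intersect(clinical$sample_id[clinical$state == "healthy"],
                           colnames(mat))
  nh <- length(healthy_ids)
  if (nh < 2) stop_("GED needs >= 2 healthy reference samples")
  H <- mat[, healthy_ids, drop = FALSE]
  h_mean <- rowMeans(H)
  h_sd <- apply(H, 1, stats::sd)
  drop_genes <- rownames(mat)[h_sd <= 0]
  if (length(drop_genes)) {
    warn_("%d gene(s) with zero healthy variance dropped from all terms",
          length(drop_genes))
  }
  usable <- setdiff(rownames(mat), drop_genes)
  term_genes <- lapply(genesets$genes, function(g) intersect(g, usable))
  keep_terms <- lengths(term_genes) >= 3
  if (!all(keep_terms)) {
    warn_("%d term(s) with < 3 mapped genes dropped", sum(!keep_terms))
  }
  if (!any(keep_terms)) stop_("no term has >= 3 mapped genes")
  term_genes <- term_genes[keep_terms]
  term_ids <- genesets$term_id[keep_terms]
  # z-scores with plug-in reference
  Zp <- (mat[usable, , drop = FALSE] - h_mean[usable]) / h_sd[usable]
  Z <- Zp
  if (loo_healthy && nh >= 3) {
    sx <- rowSums(H[usable, , drop = FALSE])
    sx2 <- rowSums(H[usable, , drop = FALSE]^2)
    for (s in healthy_ids) {
      x <- H[usable, s]
      m <- (sx - x) / (nh - 1)
      v <- (sx2 - x^2 - (nh - 1) * m^2) / (nh - 2)
      v <- pmax(v, 1e-12)
      Z[, s] <- (x - m) / sqrt(v)
    }
  }
  act <- t(vapply(term_genes, function(g) {
    if (signed) colMeans(Z[g, , drop = FALSE])
    else colMeans(abs(Z[g, , drop = FALSE]))
  }, numeric(ncol(Z))))
  rownames(act) <- term_ids
  structure(list(term_ids = term_ids, module = genesets$module[keep_terms],
                 sample_ids = colnames(Z), activity = act),
            class = "term_activity")
}

#' Hypergeometric enrichment of a gene list into functional terms
#'
#' One-sided hypergeometric (over-representation) test of the overlap
#' between a query gene list and each term, given a background universe,
#' with BH adjustment.
#'
#' @param genes Query gene list (must lie within `background`).
#' @param genesets A `geneset_collection`.
#' @param background Background gene universe.
#' @param q_max FDR threshold for the `significant` flag (default 0.01).
#' @return `data.frame`: `term_id`, `module`, `overlap`, `term_size`,
#'   `p_value`, `q_value`, `significant`.
#' @export
enrich_terms <- function(genes, genesets, background, q_max = 0.01) {
  if (!length(background)) stop_("empty background")
  background <- unique(background)
  genes <- intersect(unique(genes), background)
  N <- length(background)
  n <- length(genes)
  p <- m <- k <- integer(nrow(genesets))
  pv <- numeric(nrow(genesets))
  for (i in seq_len(nrow(genesets))) {
    term <- intersect(genesets$genes[[i]], background)
    m[i] <- length(term)
    k[i] <- length(intersect(term, genes))
    pv[i] <- stats::phyper(k[i] - 1, m[i], N - m[i], n, lower.tail = FALSE)
  }
  q <- stats::p.adjust(pv, "BH")
  data.frame(term_id = genesets$term_id, module = genesets$module,
             overlap = k, term_size = m, p_value = pv, q_value = q,
             significant = q < q_max, stringsAsFactors = FALSE)
}

#' Differential expression per subtype versus healthy controls
#'
#' Reruns the ANOVA screen separately for each subtype against the healthy
#' controls; subtypes with fewer than 2 samples are skipped with a warning.
#'
#' @param mat Expression matrix.
#' @param labels Named subtype labels for SLE samples.
#' @param clinical Clinical table.
#' @param q_max FDR threshold.
#' @return Named list of [anova_screen()] tables, one per subtype.
#' @export
subtype_deg <- function(mat, labels, clinical, q_max = 0.05) {
  healthy_ids <- intersect(clinical$sample_id[clinical$state == "healthy"],
                           colnames(mat))
  if (length(healthy_ids) < 2) stop_("need healthy samples for subtype DEGs")
  out <- list()
  for (st in unique(labels)) {
    ids <- intersect(names(labels)[labels == st], colnames(mat))
    if (length(ids) < 2) {
      warn_("subtype %s has < 2 samples; skipped", st)
      next
    }
    out[[as.character(st)]] <-
      anova_screen(mat[, c(ids, healthy_ids), drop = FALSE], clinical, q_max)
  }
  out
}

#' Module dysregulation profile per subtype
#'
#' For each (subtype, functional module) pair: the mean term activity over
#' the subtype's samples minus the healthy mean (the degree of
#' dysregulation), with a Wilcoxon rank-sum p-value against the healthy
#' per-sample module activities, BH-adjusted across the profile. Modules
#' with no surviving terms are reported with `NA`.
#'
#' @param term_activity A `term_activity`.
#' @param labels Named subtype labels.
#' @param clinical Clinical table.
#' @return `data.frame`: `subtype`, `module`, `delta`, `p_value`,
#'   `q_value`, `n_terms`.
#' @export
module_profile <- function(term_activity, labels, clinical) {
  healthy_ids <- intersect(clinical$sample_id[clinical$state == "healthy"],
                           term_activity$sample_ids)
  mods <- setdiff(GENESET_MODULES, "none")
  out <- list()
  for (st in sort(unique(as.character(labels)))) {
    ids <- intersect(names(labels)[labels == st], term_activity$sample_ids)
    for (m in mods) {
      rows <- term_activity$module == m
      if (!any(rows)) {
        out[[length(out) + 1]] <- data.frame(
          subtype = st, module = m, delta = NA_real_, p_value = NA_real_,
          n_terms = 0L, stringsAsFactors = FALSE)
        next
      }
      a_sub <- colMeans(term_activity$activity[rows, ids, drop = FALSE])
      a_h <- colMeans(term_activity$activity[rows, healthy_ids, drop = FALSE])
      p <- if (length(ids) >= 2 && length(healthy_ids) >= 2) {
        suppressWarnings(stats::wilcox.test(a_sub, a_h)$p.value)
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        subtype = st, module = m, delta = mean(a_sub) - mean(a_h),
        p_value = p, n_terms = sum(rows), stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, out)
  prof$q_value <- stats::p.adjust(prof$p_value, "BH")
  prof
}

#' Term-term similarity over a sample subset
#'
#' Pairwise Spearman correlation of term activity vectors across the chosen
#' samples (the network analysis restricts to mixed-type samples).
#' Constant-activity terms get correlation 0 against everything, with a
#' warning; the diagonal is 1.
#'
#' @param term_activity A `term_activity`.
#' @param samples Sample ids to correlate over (>= 10).
#' @return Symmetric similarity matrix with attribute `n_samples`.
#' @export
term_similarity <- function(term_activity, samples) {
  samples <- intersect(samples, term_activity$sample_ids)
  if (length(samples) < 10) stop_("term similarity needs >= 10 samples")
  A <- term_activity$activity[, samples, drop = FALSE]
  const <- apply(A, 1, stats::sd) <= 0
  if (any(const)) {
    warn_("%d constant-activity term(s); their correlations set to 0",
          sum(const))
  }
  S <- suppressWarnings(stats::cor(t(A), method = "spearman"))
  S[const, ] <- 0
  S[, const] <- 0
  diag(S) <- 1
  attr(S, "n_samples") <- length(samples)
  S
}

#' Build the term co-expression network
#'
#' Connects two terms when their activity similarity is both strong
#' (`|r| >= r_min`) and significant (BH-adjusted rank-correlation t-test
#' `q < q_max` over the upper triangle); edge weight is `|r|`. Isolated
#' nodes are retained.
#'
#' @param similarity Output of [term_similarity()] (carries `n_samples`).
#' @param r_min Minimum |correlation| for an edge (default 0.6).
#' @param q_max FDR threshold for edges (default 0.05).
#' @return An `igraph` graph with edge attribute `weight`.
#' @export
build_network <- function(similarity, r_min = 0.6, q_max = 0.05) {
  n <- attr(similarity, "n_samples")
  if (is.null(n)) stop_("similarity must come from term_similarity()")
  terms <- rownames(similarity)
  ut <- which(upper.tri(similarity), arr.ind = TRUE)
  r <- similarity[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  keep <- abs(r) >= r_min & q < q_max
  el <- cbind(terms[ut[keep, 1]], terms[ut[keep, 2]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], weight = abs(r[keep]),
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = terms)
  g
}

#' Detect communities by greedy modularity maximization
#'
#' Weighted fast-greedy modularity optimization (deterministic given the
#' node ordering). Isolated nodes form their own singleton communities.
#'
#' @param network An `igraph` graph with `weight` edge attribute.
#' @return A list: `membership` (named by term), `modularity`,
#'   `n_communities`.
#' @export
detect_communities <- function(network) {
  if (igraph::ecount(network) < 1) stop_("network has no edges")
  cm <- igraph::cluster_fast_greedy(network,
                                    weights = igraph::E(network)$weight)
  mem <- stats::setNames(igraph::membership(cm),
                         igraph::V(network)$name)
  list(membership = mem, modularity = max(cm$modularity),
       n_communities = length(unique(mem)))
}

#' Rank bridge terms between network communities
#'
#' Ranks terms by betweenness centrality restricted to shortest paths
#' whose endpoints lie in different communities -- the nodes carrying the
#' cross-community traffic. Path lengths use distance `1 - weight` (a
#' strong correlation is a short edge). Disconnected community pairs
#' contribute nothing; with a single community the result is empty (with a
#' warning).
#'
#' @param network An `igraph` graph.
#' @param communities Output of [detect_communities()].
#' @param top_n Number of terms to return (default 5).
#' @return `data.frame`: `term_id`, `bridge_score`, sorted descending.
#' @export
bridge_nodes <- function(network, communities, top_n = 5) {
  mem <- communities$membership
  if (length(unique(mem)) < 2) {
    warn_("single community; no bridge nodes")
    return(data.frame(term_id = character(0), bridge_score = numeric(0)))
  }
  g <- network
  igraph::E(g)$dist <- pmax(1 - igraph::E(g)$weight, 1e-9)
  vs <- igraph::V(g)$name
  score <- stats::setNames(numeric(length(vs)), vs)
  for (i in seq_along(vs)) {
    for (j in seq_along(vs)) {
      if (j <= i) next
      if (mem[[vs[i]]] == mem[[vs[j]]]) next
      sp <- suppressWarnings(igraph::all_shortest_paths(
        g, from = vs[i], to = vs[j], weights = igraph::E(g)$dist))
      paths <- sp$res %||% sp$vpaths
      if (!length(paths)) next
      for (pth in paths) {
        inner <- setdiff(names(pth), c(vs[i], vs[j]))
        score[inner] <- score[inner] + 1 / length(paths)
      }
    }
  }
  ord <- order(score, decreasing = TRUE)
  out <- data.frame(term_id = vs[ord], bridge_score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out[out$bridge_score > 0, , drop = FALSE], top_n)
}

#' Write a term network to GraphML
#'
#' Attaches the community membership as a vertex attribute and writes
#' standard GraphML (readable by Cytoscape/Gephi).
#'
#' @param network An `igraph` graph.
#' @param communities Optional [detect_communities()] output.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path, communities = NULL) {
  if (!is.null(communities)) {
    igraph::V(network)$community <-
      as.integer(communities$membership[igraph::V(network)$name])
  }
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
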