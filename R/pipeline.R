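# Stage runners: each reads/writes the on-disk representations and is the
# surface the command-line wrapper (inst/scripts/lupus-ssc) calls. All
# outputs are plain text and deterministic given the stage seed.

#' Default pipeline thresholds
#'
#' One place for every tunable threshold; [read_pipeline_config()] merges a
#' YAML file over these defaults.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(sd_min = 0.1, split_seed = 1L, q_max = 0.05, score_min = 0.6,
       n_perm = 1000L, min_visits = 3L, cor_method = "spearman",
       k_range = c(2L, 6L), r_min = 0.6, edge_q_max = 0.05,
       enrich_q_max = 0.01, top_bridges = 5L, seed = 1L)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys override [pipeline_defaults()].
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  cfg
}

#' @noRd
write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read term activity as TSV
#'
#' `term_id`, `module`, then one column per sample.
#'
#' @param term_activity A `term_activity`.
#' @param path File path.
#' @export
write_term_activity <- function(term_activity, path) {
  df <- data.frame(term_id = term_activity$term_ids,
                   module = term_activity$module,
                   term_activity$activity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_term_activity
#' @export
read_term_activity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  act <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(act) <- df$term_id
  structure(list(term_ids = df$term_id, module = df$module,
                 sample_ids = colnames(act), activity = act),
            class = "term_activity")
}

#' Simulate a cohort to disk
#'
#' Writes `expression.tsv`, `clinical.csv`, `truth.json`, `genesets.gmt`
#' and `modules.tsv` (the term -> module map) under `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param terms_per_module,term_size,n_decoy,include_bridge Passed to
#'   [build_term_collection()].
#' @return Invisibly, the generated cohort list.
#' @export
run_simulate <- function(config, out_dir, terms_per_module = 4,
                         term_size = 10, n_decoy = 10,
                         include_bridge = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(config)
  write_expression(coh$expression, file.path(out_dir, "expression.tsv"))
  write_clinical(coh$clinical, file.path(out_dir, "clinical.csv"))
  gs <- build_term_collection(coh$truth, rownames(coh$expression),
                              terms_per_module, term_size, n_decoy,
                              include_bridge, seed = config$seed + 1L)
  write_gmt(gs, file.path(out_dir, "genesets.gmt"),
            module_map = file.path(out_dir, "modules.tsv"))
  tr <- coh$truth
  tr$planted_drug_effects <- lapply(tr$planted_drug_effects, as.list)
  jsonlite::write_json(unclass(tr), file.path(out_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(coh)
}

#' Preprocess a cohort from disk
#'
#' Runs [preprocess_pipeline()] and writes `expression_norm.tsv`,
#' `clinical_filtered.csv`, `split.json` and `exclusions.tsv`.
#'
#' @param expression_path,clinical_path Input files.
#' @param out_dir Output directory.
#' @param sd_min,split_seed See [preprocess_pipeline()].
#' @return Invisibly, the preprocessing result list.
#' @export
run_preprocess <- function(expression_path, clinical_path, out_dir,
                           sd_min = 0.1, split_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression(expression_path)
  clin <- read_clinical(clinical_path)
  res <- preprocess_pipeline(mat, clin, sd_min, split_seed)
  write_expression(res$expression, file.path(out_dir, "expression_norm.tsv"))
  write_clinical(res$clinical, file.path(out_dir, "clinical_filtered.csv"))
  jsonlite::write_json(res$split, file.path(out_dir, "split.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  write_tsv_(res$exclusions, file.path(out_dir, "exclusions.tsv"))
  invisible(res)
}

#' Run the signature screen from disk
#'
#' Writes `signature.tsv` (gene, F, p, q, score, perm_p, selected).
#'
#' @param expression_path,clinical_path Input files (preprocessed).
#' @param out_dir Output directory.
#' @param q_max,score_min,n_perm,min_visits,seed,method
#'   See [signature_screen()].
#' @return Invisibly, the screen result list.
#' @export
run_signature <- function(expression_path, clinical_path, out_dir,
                          q_max = 0.05, score_min = 0.6, n_perm = 1000,
                          min_visits = 3, seed = 1L, method = "spearman") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression(expression_path)
  clin <- read_clinical(clinical_path)
  res <- signature_screen(mat, clin, q_max, score_min, n_perm, min_visits,
                          seed, method)
  write_tsv_(res$result, file.path(out_dir, "signature.tsv"))
  invisible(res)
}

#' Train the SSC from disk
#'
#' Trains on the SLE samples and writes `model.json` plus
#' `training_labels.tsv`.
#'
#' @param expression_path,clinical_path Input files.
#' @param signature_path `signature.tsv` from [run_signature()] (or any
#'   TSV with `gene` and `selected` columns).
#' @param out_dir Output directory.
#' @param k,k_range,seed See [train_ssc()].
#' @return Invisibly, the training result list.
#' @export
run_train_ssc <- function(expression_path, clinical_path, signature_path,
                          out_dir, k = NULL, k_range = 2:6, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression(expression_path)
  clin <- read_clinical(clinical_path)
  sig <- utils::read.delim(signature_path, stringsAsFactors = FALSE)
  genes <- if ("selected" %in% names(sig)) sig$gene[sig$selected] else sig$gene
  sle_ids <- intersect(clin$sample_id[clin$state == "SLE"], colnames(mat))
  fit <- train_ssc(mat[, sle_ids, drop = FALSE], genes, k, k_range, seed)
  save_ssc(fit$model, file.path(out_dir, "model.json"))
  write_tsv_(data.frame(sample_id = names(fit$labels),
                        cluster = unname(fit$labels)),
             file.path(out_dir, "training_labels.tsv"))
  invisible(fit)
}

#' Classify samples from disk
#'
#' Writes `assignments.tsv` (sample, cluster, subtype, distances,
#' likelihoods).
#'
#' @param model_path JSON model from [run_train_ssc()].
#' @param expression_path Samples to classify.
#' @param out_dir Output directory.
#' @return Invisibly, the assignment `data.frame`.
#' @export
run_classify <- function(model_path, expression_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_ssc(model_path)
  mat <- read_expression(expression_path)
  asg <- ssc_classify(model, mat)
  write_tsv_(asg, file.path(out_dir, "assignments.tsv"))
  invisible(asg)
}

#' Functional profiling from disk
#'
#' GED term activity, signature enrichment and the per-subtype module
#' profile; writes `activity.tsv`, `enrichment.tsv`, `module_profile.tsv`.
#'
#' @param expression_path,clinical_path Input files.
#' @param assignments_path `assignments.tsv` from [run_classify()].
#' @param gmt_path,module_map_path Gene sets and term -> module map.
#' @param signature_path Optional `signature.tsv` for the enrichment query.
#' @param out_dir Output directory.
#' @param enrich_q_max FDR threshold for enrichment.
#' @return Invisibly, a list with `activity`, `enrichment`, `profile`.
#' @export
run_functional <- function(expression_path, clinical_path, assignments_path,
                           gmt_path, module_map_path = NULL,
                           signature_path = NULL, out_dir,
                           enrich_q_max = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression(expression_path)
  clin <- read_clinical(clinical_path)
  gs <- read_gmt(gmt_path, module_map_path)
  asg <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(asg$subtype, asg$sample_id)
  act <- ged_activity(mat, clin, gs)
  write_term_activity(act, file.path(out_dir, "activity.tsv"))
  enr <- NULL
  if (!is.null(signature_path)) {
    sig <- utils::read.delim(signature_path, stringsAsFactors = FALSE)
    genes <- if ("selected" %in% names(sig)) sig$gene[sig$selected] else sig$gene
    enr <- enrich_terms(genes, gs, rownames(mat), enrich_q_max)
    write_tsv_(enr, file.path(out_dir, "enrichment.tsv"))
  }
  prof <- module_profile(act, labels, clin)
  write_tsv_(prof, file.path(out_dir, "module_profile.tsv"))
  invisible(list(activity = act, enrichment = enr, profile = prof))
}

#' Build the term network from disk
#'
#' Restricts to the samples of one subtype (the mixed type in the study
#' design), builds the similarity network, detects communities and ranks
#' bridge nodes; writes `network.graphml`, `communities.tsv` and
#' `bridges.tsv`.
#'
#' @param activity_path `activity.tsv` from [run_functional()].
#' @param assignments_path `assignments.tsv`.
#' @param subtype Subtype whose samples define the similarity
#'   (default `"mixed"`).
#' @param out_dir Output directory.
#' @param r_min,edge_q_max Edge thresholds ([build_network()]).
#' @param top_bridges Number of bridge nodes to report.
#' @return Invisibly, a list with `network`, `communities`, `bridges`.
#' @export
run_network <- function(activity_path, assignments_path, subtype = "mixed",
                        out_dir, r_min = 0.6, edge_q_max = 0.05,
                        top_bridges = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  act <- read_term_activity(activity_path)
  asg <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  ids <- asg$sample_id[asg$subtype == subtype]
  sim <- term_similarity(act, ids)
  net <- build_network(sim, r_min, edge_q_max)
  com <- detect_communities(net)
  br <- bridge_nodes(net, com, top_bridges)
  write_network_graphml(net, file.path(out_dir, "network.graphml"), com)
  write_tsv_(data.frame(term_id = names(com$membership),
                        community = as.integer(com$membership)),
             file.path(out_dir, "communities.tsv"))
  write_tsv_(br, file.path(out_dir, "bridges.tsv"))
  invisible(list(network = net, communities = com, bridges = br))
}

#' Treatment analyses from disk
#'
#' Writes `deltas.tsv`, `drug_benefit.tsv`, `reposition.tsv` and
#' `demographics.tsv`.
#'
#' @param clinical_path Clinical table.
#' @param assignments_path `assignments.tsv`.
#' @param out_dir Output directory.
#' @param seed Seed for any Monte-Carlo Fisher test.
#' @return Invisibly, a list with the four result objects.
#' @export
run_treatment <- function(clinical_path, assignments_path, out_dir,
                          seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clin <- read_clinical(clinical_path)
  asg <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(asg$subtype, asg$sample_id)
  deltas <- sledai_deltas(clin, labels)
  benefit <- drug_benefit(deltas)
  repos <- if (any(clin$drug_ifnk, na.rm = TRUE)) {
    reposition_rates(clin, labels, "ifnk")
  } else NULL
  demo <- list()
  for (v in c("age_group", "sex", "race")) {
    demo[[v]] <- tryCatch(demographic_association(labels, clin, v, seed = seed),
                          error = function(e) NULL)
  }
  write_tsv_(deltas, file.path(out_dir, "deltas.tsv"))
  write_tsv_(benefit, file.path(out_dir, "drug_benefit.tsv"))
  if (!is.null(repos)) write_tsv_(repos, file.path(out_dir, "reposition.tsv"))
  dd <- do.call(rbind, lapply(names(demo), function(v) {
    if (is.null(demo[[v]])) return(NULL)
    data.frame(variable = v, p_value = demo[[v]]$p_value,
               method = demo[[v]]$method, stringsAsFactors = FALSE)
  }))
  if (!is.null(dd)) write_tsv_(dd, file.path(out_dir, "demographics.tsv"))
  invisible(list(deltas = deltas, drug_benefit = benefit,
                 reposition = repos, demographics = demo))
}
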