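#' Configuration for the synthetic longitudinal SLE cohort generator
#'
#' Defines the study conditions the generator emulates: repeated visits per
#' patient with varying visit counts, SLEDAI trajectories, a block of
#' "activity" genes whose expression tracks SLEDAI, three latent subtypes
#' defined by elevation of an IFN gene module, an NE (neutrophil) gene
#' module, or both, healthy controls, and drug-exposure effects on SLEDAI
#' slopes.
#'
#' The SLEDAI trajectory model is a patient-level baseline (subtype-specific
#' mean, severity ordering mixed > IFN-high > NE-high) plus per-month drug
#' slope effects and rounded Gaussian visit noise, clipped to
#' `sledai_range`. Activity-gene expression is
#' `baseline + sign * beta * SLEDAI + noise` with `beta` calibrated so the
#' within-patient correlation with SLEDAI is `activity_cor` in expectation
#' given `noise_sd` and `sledai_sd`. Module genes of an elevated module gain
#' `effect_size` plus a per-sample intensity factor with standard deviation
#' `module_factor_sd`, emulating the varying strength of the IFN/NE
#' signatures across patients.
#'
#' @param n_patients Number of SLE patients.
#' @param visits_min,visits_max Range of visits per patient (uniform).
#' @param n_healthy Number of healthy control samples (one visit each).
#' @param n_genes Total number of genes.
#' @param n_activity_genes Genes correlated with SLEDAI.
#' @param ifn_module_size,ne_module_size Sizes of the planted IFN / NE
#'   modules (disjoint gene sets).
#' @param subtype_props Named proportions for `mixed`, `IFN-high`,
#'   `NE-high`; must sum to 1.
#' @param effect_size Mean log2 shift of elevated module genes.
#' @param mixed_boost Multiplier on `effect_size` for mixed-subtype
#'   samples (default 1.25): the mixed group is the most dysregulated in
#'   every module, reproducing the observed severity ordering.
#' @param activity_cor Target within-patient |correlation| of activity
#'   genes with SLEDAI, in (0, 1).
#' @param activity_ifn_overlap Fraction of activity genes drawn from the
#'   IFN module (the signature and the IFN signature overlap in real
#'   cohorts; default 0.3).
#' @param noise_sd Gaussian expression noise SD (log2 units).
#' @param module_factor_sd SD of the per-sample module intensity factor.
#' @param sledai_range Integer `(lo, hi)` clip range for SLEDAI.
#' @param sledai_means Named subtype baseline means (severity ordering).
#' @param sledai_sd Visit-level SLEDAI noise SD (score points).
#' @param sledai_between_sd Patient-level baseline SD.
#' @param visit_gap_days `(lo, hi)` uniform range of days between visits.
#' @param drug_effects Named list `drug -> named numeric by subtype` of
#'   SLEDAI slope shifts (score points per month) while exposed. Drugs:
#'   `cs`, `hc`, `is`.
#' @param drug_prob Probability an SLE patient is exposed to each drug
#'   (constant over visits).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 60, visits_min = 4, visits_max = 8,
                       n_healthy = 30, n_genes = 2000,
                       n_activity_genes = 50,
                       ifn_module_size = 30, ne_module_size = 30,
                       subtype_props = c("mixed" = 1/3, "IFN-high" = 1/3,
                                         "NE-high" = 1/3),
                       effect_size = 1.5, mixed_boost = 1.25,
                       activity_cor = 0.8,
                       activity_ifn_overlap = 0.3,
                       noise_sd = 0.5, module_factor_sd = 0.3,
                       sledai_range = c(0L, 24L),
                       sledai_means = c("mixed" = 10, "IFN-high" = 7,
                                        "NE-high" = 4),
                       sledai_sd = 2, sledai_between_sd = 2,
                       visit_gap_days = c(30, 90),
                       drug_effects = list(),
                       drug_prob = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(subtype_props) - 1) > 1e-9) stop_("subtype_props must sum to 1")
  if (!setequal(names(subtype_props), SUBTYPE_LEVELS)) {
    stop_("subtype_props must be named %s", paste(SUBTYPE_LEVELS, collapse = ", "))
  }
  if (n_activity_genes > n_genes) stop_("n_activity_genes exceeds n_genes")
  if (ifn_module_size + ne_module_size > n_genes) {
    stop_("module sizes exceed n_genes")
  }
  if (noise_sd <= 0) stop_("noise_sd must be > 0")
  if (n_activity_genes > 0 && (activity_cor <= 0 || activity_cor >= 1)) {
    stop_("activity_cor = %g is infeasible with Gaussian noise; feasible range is (0, 1)",
          activity_cor)
  }
  if (visits_min < 1 || visits_max < visits_min) stop_("bad visits range")
  for (d in names(drug_effects)) {
    if (!d %in% c("cs", "hc", "is", "ifnk")) stop_("unknown drug '%s'", d)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Gene architecture shared by cohort and trial generators.
#' @noRd
plant_genes <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  idx <- sample.int(cfg$n_genes, cfg$ifn_module_size + cfg$ne_module_size)
  ifn <- genes[idx[seq_len(cfg$ifn_module_size)]]
  ne <- genes[idx[cfg$ifn_module_size + seq_len(cfg$ne_module_size)]]
  n_ov <- min(round(cfg$activity_ifn_overlap * cfg$n_activity_genes),
              cfg$ifn_module_size)
  pool <- setdiff(genes, c(ifn, ne))
  n_rest <- cfg$n_activity_genes - n_ov
  if (n_rest > length(pool)) stop_("not enough genes outside modules for activity set")
  act <- c(sample(ifn, n_ov), sample(pool, n_rest))
  beta <- if (cfg$n_activity_genes > 0) {
    cfg$activity_cor * cfg$noise_sd /
      (cfg$sledai_sd * sqrt(1 - cfg$activity_cor^2))
  } else 0
  list(
    genes = genes,
    baseline = stats::setNames(stats::rnorm(cfg$n_genes, 7, 1), genes),
    ifn_genes = ifn, ne_genes = ne, activity_genes = act,
    sign = stats::setNames(sample(c(-1, 1), length(act), replace = TRUE), act),
    beta = beta
  )
}

# Expression for a set of samples given subtype and SLEDAI per sample.
# Healthy samples (subtype NA, SLEDAI 0) get baseline + noise only.
#' @noRd
simulate_expression <- function(cfg, plant, subtype, sledai) {
  ns <- length(subtype)
  E <- matrix(stats::rnorm(cfg$n_genes * ns, 0, cfg$noise_sd),
              nrow = cfg$n_genes) + plant$baseline
  dimnames(E) <- list(plant$genes, names(subtype))
  ifn_on <- !is.na(subtype) & subtype %in% c("mixed", "IFN-high")
  ne_on <- !is.na(subtype) & subtype %in% c("mixed", "NE-high")
  boost <- ifelse(!is.na(subtype) & subtype == "mixed", cfg$mixed_boost, 1)
  if (any(ifn_on)) {
    lift <- cfg$effect_size * boost[ifn_on] +
      stats::rnorm(sum(ifn_on), 0, cfg$module_factor_sd)
    E[plant$ifn_genes, ifn_on] <-
      E[plant$ifn_genes, ifn_on, drop = FALSE] + rep(lift, each = length(plant$ifn_genes))
  }
  if (any(ne_on)) {
    lift <- cfg$effect_size * boost[ne_on] +
      stats::rnorm(sum(ne_on), 0, cfg$module_factor_sd)
    E[plant$ne_genes, ne_on] <-
      E[plant$ne_genes, ne_on, drop = FALSE] + rep(lift, each = length(plant$ne_genes))
  }
  if (length(plant$activity_genes)) {
    E[plant$activity_genes, ] <- E[plant$activity_genes, , drop = FALSE] +
      plant$beta * outer(plant$sign, sledai)
  }
  E
}

# sample() treats a scalar first argument as 1:n; guard the degenerate range
#' @noRd
sample_visits <- function(lo, hi, n) {
  if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

#' @noRd
sample_demographics <- function(n) {
  data.frame(
    age_group = sample(c("pediatric", "adult"), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.9, 0.1)),
    race = sample(c("black", "white", "other"), n, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic longitudinal SLE cohort
#'
#' Emits an expression matrix, a clinical table and the planted ground
#' truth, fully reproducible from `config$seed`. See [sim_config()] for the
#' generative model.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (genes x samples matrix),
#'   `clinical` (per-visit `data.frame`) and `truth` (class `ground_truth`:
#'   `subtype_of_patient`, `activity_genes`, `ifn_genes`, `ne_genes`,
#'   `planted_drug_effects`, plus the calibration slope `beta`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

#' @noRd
generate_cohort_impl <- function(cfg) {
  pid <- sprintf("P%03d", seq_len(cfg$n_patients))
  subtype <- stats::setNames(
    sample(SUBTYPE_LEVELS, cfg$n_patients, replace = TRUE,
           prob = cfg$subtype_props[SUBTYPE_LEVELS]), pid)
  n_visits <- sample_visits(cfg$visits_min, cfg$visits_max, cfg$n_patients)
  demo <- sample_demographics(cfg$n_patients)
  drugs <- c("cs", "hc", "is")
  exposure <- matrix(stats::runif(cfg$n_patients * 3) < cfg$drug_prob,
                     ncol = 3, dimnames = list(pid, drugs))
  base_sledai <- stats::rnorm(cfg$n_patients,
                              cfg$sledai_means[subtype], cfg$sledai_between_sd)
  rows <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    v <- n_visits[i]
    gaps <- stats::runif(v - 1, cfg$visit_gap_days[1], cfg$visit_gap_days[2])
    t_days <- c(0, cumsum(gaps))
    slope <- 0
    for (d in drugs) {
      if (exposure[i, d] && !is.null(cfg$drug_effects[[d]])) {
        slope <- slope + cfg$drug_effects[[d]][[subtype[i]]]
      }
    }
    s <- round(base_sledai[i] + slope * t_days / DAYS_PER_MONTH +
                 stats::rnorm(v, 0, cfg$sledai_sd))
    s <- pmin(pmax(s, cfg$sledai_range[1]), cfg$sledai_range[2])
    rows[[i]] <- data.frame(
      patient_id = pid[i], sample_id = NA_character_,
      visit_index = seq_len(v) - 1L, time_days = t_days, sledai = s,
      state = "SLE", age_group = demo$age_group[i], sex = demo$sex[i],
      race = demo$race[i],
      drug_cs = exposure[i, "cs"], drug_hc = exposure[i, "hc"],
      drug_is = exposure[i, "is"], drug_ifnk = FALSE,
      cohort = if (i %% 2 == 1) "cohortA" else "cohortB",
      stringsAsFactors = FALSE
    )
  }
  clin <- do.call(rbind, rows)
  if (cfg$n_healthy > 0) {
    hdemo <- sample_demographics(cfg$n_healthy)
    clin <- rbind(clin, data.frame(
      patient_id = sprintf("H%03d", seq_len(cfg$n_healthy)),
      sample_id = NA_character_, visit_index = 0L, time_days = 0,
      sledai = 0L, state = "healthy", age_group = hdemo$age_group,
      sex = hdemo$sex, race = hdemo$race,
      drug_cs = FALSE, drug_hc = FALSE, drug_is = FALSE, drug_ifnk = FALSE,
      cohort = rep_len(c("cohortA", "cohortB"), cfg$n_healthy),
      stringsAsFactors = FALSE
    ))
  }
  clin$sample_id <- sprintf("S%04d", seq_len(nrow(clin)))
  plant <- plant_genes(cfg)
  samp_subtype <- stats::setNames(
    ifelse(clin$state == "SLE", subtype[clin$patient_id], NA_character_),
    clin$sample_id)
  samp_sledai <- stats::setNames(ifelse(clin$state == "SLE", clin$sledai, 0),
                                 clin$sample_id)
  expr <- simulate_expression(cfg, plant, samp_subtype, samp_sledai)
  truth <- structure(list(
    subtype_of_patient = subtype,
    subtype_of_sample = samp_subtype,
    activity_genes = plant$activity_genes,
    ifn_genes = plant$ifn_genes, ne_genes = plant$ne_genes,
    activity_sign = plant$sign, beta = plant$beta,
    planted_drug_effects = cfg$drug_effects
  ), class = "ground_truth")
  list(expression = expr, clinical = validate_clinical(clin), truth = truth)
}

#' Generate a synthetic targeted-treatment trial
#'
#' Emulates a small longitudinal vaccine-trial follow-up: every patient is
#' treated (the `drug_ifnk` flag is set) and assessed at regular quarterly
#' visits; the SLEDAI slope per month of each patient equals the configured
#' per-subtype treatment effect in expectation. Subtype counts are assigned
#' deterministically from `subtype_props` (largest-remainder rounding), so
#' tiny trials keep every arm populated. Trial baselines are the cohort
#' subtype means + 3 (an active-disease entry criterion).
#'
#' @param config A [sim_config()]; `n_patients` and `visits_min/max` size
#'   the trial, `sledai_sd` is the assessment noise.
#' @param treatment_effects Named numeric, SLEDAI slope per month for each
#'   of `mixed`, `IFN-high`, `NE-high` (negative = benefit).
#' @return As [generate_cohort()]; `truth$planted_drug_effects$ifnk` holds
#'   the configured effects. `n_patients = 0` yields empty outputs.
#' @export
generate_trial <- function(config, treatment_effects) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(names(treatment_effects), SUBTYPE_LEVELS)) {
    stop_("treatment_effects must be named %s",
          paste(SUBTYPE_LEVELS, collapse = ", "))
  }
  withr::with_seed(config$seed, generate_trial_impl(config, treatment_effects))
}

#' @noRd
generate_trial_impl <- function(cfg, eff) {
  n <- cfg$n_patients
  pid <- sprintf("T%03d", seq_len(n))
  # largest-remainder apportionment of subtype counts
  quota <- cfg$subtype_props[SUBTYPE_LEVELS] * n
  cnt <- floor(quota)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(quota - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  subtype <- stats::setNames(rep(SUBTYPE_LEVELS, times = cnt), pid)
  demo <- sample_demographics(max(n, 1))
  gap_days <- 3 * DAYS_PER_MONTH
  base <- stats::rnorm(n, cfg$sledai_means[subtype] + 3, cfg$sledai_between_sd)
  n_visits <- sample_visits(cfg$visits_min, cfg$visits_max, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- n_visits[i]
    t_days <- (seq_len(v) - 1) * gap_days
    s <- round(base[i] + eff[[subtype[i]]] * t_days / DAYS_PER_MONTH +
                 stats::rnorm(v, 0, cfg$sledai_sd))
    s <- pmin(pmax(s, cfg$sledai_range[1]), cfg$sledai_range[2])
    rows[[i]] <- data.frame(
      patient_id = pid[i], sample_id = NA_character_,
      visit_index = seq_len(v) - 1L, time_days = t_days, sledai = s,
      state = "SLE", age_group = demo$age_group[i], sex = demo$sex[i],
      race = demo$race[i],
      drug_cs = FALSE, drug_hc = FALSE, drug_is = FALSE, drug_ifnk = TRUE,
      cohort = "trial", stringsAsFactors = FALSE
    )
  }
  clin <- if (n > 0) do.call(rbind, rows) else
    utils::read.csv(text = paste(CLINICAL_COLUMNS, collapse = ","))
  if (n > 0) clin$sample_id <- sprintf("TS%04d", seq_len(nrow(clin)))
  plant <- plant_genes(cfg)
  samp_subtype <- stats::setNames(subtype[clin$patient_id], clin$sample_id)
  samp_sledai <- stats::setNames(clin$sledai, clin$sample_id)
  expr <- simulate_expression(cfg, plant, samp_subtype,
                              if (n > 0) samp_sledai else numeric(0))
  truth <- structure(list(
    subtype_of_patient = subtype,
    subtype_of_sample = samp_subtype,
    activity_genes = plant$activity_genes,
    ifn_genes = plant$ifn_genes, ne_genes = plant$ne_genes,
    activity_sign = plant$sign, beta = plant$beta,
    planted_drug_effects = list(ifnk = as.list(eff))
  ), class = "ground_truth")
  if (n > 0) clin <- validate_clinical(clin)
  list(expression = expr, clinical = clin, truth = truth)
}

#' Build a term collection over the planted gene modules
#'
#' Constructs GMT-style functional terms from a cohort's ground truth: IFN
#' and viral-infection terms sample the planted IFN module, bacterial and
#' fungal terms sample the planted NE module, immune-disorder terms sample
#' the activity genes, and decoy terms sample unplanted genes. Optionally
#' adds one cross-module "bridge" term drawing half its genes from each of
#' the IFN and NE modules (a term tied to both latent factors).
#'
#' @param truth A `ground_truth` from [generate_cohort()].
#' @param all_genes Character vector of all gene ids in the matrix.
#' @param terms_per_module Terms generated per functional module.
#' @param term_size Genes per term (capped at the source pool size).
#' @param n_decoy Number of decoy terms from unplanted genes.
#' @param include_bridge Add the cross-module bridge term.
#' @param seed Seed for the term sampling.
#' @return A `geneset_collection`.
#' @export
build_term_collection <- function(truth, all_genes, terms_per_module = 4,
                                  term_size = 10, n_decoy = 10,
                                  include_bridge = FALSE, seed = 1L) {
  withr::with_seed(seed, {
    # Module terms sample the non-signature module genes: activity genes
    # track SLEDAI in every patient, so terms containing them would read
    # "elevated" in all subtypes and mask the module pattern.
    ifn_pure <- setdiff(truth$ifn_genes, truth$activity_genes)
    ne_pure <- setdiff(truth$ne_genes, truth$activity_genes)
    pools <- list(
      IFN = ifn_pure, viral = ifn_pure,
      bacterial = ne_pure, fungal = ne_pure,
      immune = truth$activity_genes
    )
    ids <- character(0); mods <- character(0); genes <- list()
    for (m in names(pools)) {
      pool <- pools[[m]]
      if (!length(pool)) next
      for (j in seq_len(terms_per_module)) {
        ids <- c(ids, sprintf("%s_term_%d", m, j))
        mods <- c(mods, m)
        genes <- c(genes, list(sample(pool, min(term_size, length(pool)))))
      }
    }
    decoy_pool <- setdiff(all_genes,
                          c(truth$ifn_genes, truth$ne_genes, truth$activity_genes))
    for (j in seq_len(n_decoy)) {
      ids <- c(ids, sprintf("decoy_term_%d", j))
      mods <- c(mods, "none")
      genes <- c(genes, list(sample(decoy_pool, min(term_size, length(decoy_pool)))))
    }
    if (include_bridge) {
      h <- max(1, term_size %/% 2)
      ids <- c(ids, "bridge_IFN_NE")
      mods <- c(mods, "none")
      genes <- c(genes, list(c(sample(ifn_pure, min(h, length(ifn_pure))),
                               sample(ne_pure, min(h, length(ne_pure))))))
    }
    geneset_collection(ids, genes, module = mods)
  })
}
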