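# Subtype-stratified treatment-benefit statistics: per-patient SLEDAI
# change rates, drug-exposure contrasts, targeted-drug repositioning rates,
# and demographic association tests.

#' Per-patient SLEDAI change and per-month rate
#'
#' For each SLE patient with at least two visits: the total SLEDAI change
#' (last minus first visit), the elapsed time in months (30.44 days per
#' month), and the change rate per month. The patient-level subtype is the
#' majority label over the patient's samples (ties broken by the earliest
#' sample's label). Single-visit patients and patients with zero elapsed
#' time are skipped with a warning.
#'
#' @param clinical Clinical table.
#' @param assignments Named subtype labels by sample id (e.g. the
#'   `subtype` column of [ssc_classify()] output, named by `sample_id`).
#' @return `data.frame`: `patient_id`, `subtype`, drug flags,
#'   `delta_total`, `months`, `rate`.
#' @export
sledai_deltas <- function(clinical, assignments) {
  sle <- clinical[clinical$state == "SLE", , drop = FALSE]
  sle <- sle[order(sle$patient_id, sle$time_days), , drop = FALSE]
  out <- list()
  for (p in unique(sle$patient_id)) {
    rows <- sle[sle$patient_id == p, , drop = FALSE]
    if (nrow(rows) < 2) {
      warn_("patient %s has a single visit; skipped", p)
      next
    }
    months <- (rows$time_days[nrow(rows)] - rows$time_days[1]) / DAYS_PER_MONTH
    if (months <= 0) {
      warn_("patient %s has zero elapsed time; skipped", p)
      next
    }
    labs <- assignments[rows$sample_id]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) stop_("no subtype assignments for patient %s", p)
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    subtype <- if (length(top) == 1) top else labs[labs %in% top][1]
    delta <- rows$sledai[nrow(rows)] - rows$sledai[1]
    out[[p]] <- data.frame(
      patient_id = p, subtype = unname(subtype),
      drug_cs = rows$drug_cs[1], drug_hc = rows$drug_hc[1],
      drug_is = rows$drug_is[1], drug_ifnk = rows$drug_ifnk[1],
      delta_total = delta, months = months, rate = delta / months,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Drug benefit per subtype
#'
#' For each (subtype, drug) pair, compares the SLEDAI change rate of
#' exposed versus unexposed patients (Wilcoxon rank-sum, BH-adjusted
#' across the table). The effect is the difference of mean rates (exposed
#' minus unexposed; negative = benefit). Cells with fewer than 2 patients
#' on either side skip the test but still report counts. A `rank` column
#' orders drugs within each subtype by effect (most beneficial first).
#'
#' @param deltas Output of [sledai_deltas()].
#' @param drugs Drug flags to compare (default `cs`, `hc`, `is`).
#' @param use_rate Compare per-month rates (default) or total changes.
#' @return `data.frame`: `subtype`, `drug`, `n_exposed`, `n_unexposed`,
#'   `mean_exposed`, `mean_unexposed`, `difference`, `p_value`, `q_value`,
#'   `rank`.
#' @export
drug_benefit <- function(deltas, drugs = c("cs", "hc", "is"),
                         use_rate = TRUE) {
  val <- if (use_rate) deltas$rate else deltas$delta_total
  out <- list()
  for (st in sort(unique(deltas$subtype))) {
    for (d in drugs) {
      flag <- deltas[[paste0("drug_", d)]]
      inc <- deltas$subtype == st
      e <- val[inc & flag]
      u <- val[inc & !flag]
      p <- if (length(e) >= 2 && length(u) >= 2) {
        suppressWarnings(stats::wilcox.test(e, u)$p.value)
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        subtype = st, drug = d, n_exposed = length(e),
        n_unexposed = length(u),
        mean_exposed = if (length(e)) mean(e) else NA_real_,
        mean_unexposed = if (length(u)) mean(u) else NA_real_,
        difference = if (length(e) && length(u)) mean(e) - mean(u) else NA_real_,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$q_value <- stats::p.adjust(tab$p_value, "BH")
  tab$rank <- stats::ave(tab$difference, tab$subtype,
                         FUN = function(x) rank(x, ties.method = "first",
                                                na.last = "keep"))
  tab
}

#' Per-subtype SLEDAI change rates under a targeted drug
#'
#' Each consecutive inter-visit interval of a treated patient contributes
#' its SLEDAI change per month, attributed to the subtype of the
#' interval's first sample (subtype can change within a patient, so
#' attribution is at the interval level). The per-subtype rate is the mean
#' over its intervals; subtypes with zero intervals report `NA`.
#'
#' @param clinical Clinical table.
#' @param assignments Named subtype labels by sample id.
#' @param drug Drug flag selecting treated patients (default `"ifnk"`).
#' @return `data.frame`: `subtype`, `rate`, `n_intervals`, `n_samples`.
#' @export
reposition_rates <- function(clinical, assignments, drug = "ifnk") {
  flag <- clinical[[paste0("drug_", drug)]]
  tr <- clinical[clinical$state == "SLE" & flag, , drop = FALSE]
  tr <- tr[order(tr$patient_id, tr$time_days), , drop = FALSE]
  rates <- list()
  for (p in unique(tr$patient_id)) {
    rows <- tr[tr$patient_id == p, , drop = FALSE]
    if (nrow(rows) < 2) next
    for (i in seq_len(nrow(rows) - 1)) {
      dm <- (rows$time_days[i + 1] - rows$time_days[i]) / DAYS_PER_MONTH
      if (dm <= 0) next
      rates[[length(rates) + 1]] <- data.frame(
        subtype = unname(assignments[rows$sample_id[i]]),
        rate = (rows$sledai[i + 1] - rows$sledai[i]) / dm,
        stringsAsFactors = FALSE)
    }
  }
  iv <- if (length(rates)) do.call(rbind, rates) else
    data.frame(subtype = character(0), rate = numeric(0))
  subtypes <- sort(unique(c(iv$subtype, unname(assignments[tr$sample_id]))))
  n_samp <- table(factor(unname(assignments[tr$sample_id]), levels = subtypes))
  out <- data.frame(
    subtype = subtypes,
    rate = vapply(subtypes, function(s) {
      r <- iv$rate[iv$subtype == s]
      if (length(r)) mean(r) else NA_real_
    }, numeric(1)),
    n_intervals = vapply(subtypes, function(s) sum(iv$subtype == s),
                         integer(1)),
    n_samples = as.integer(n_samp),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Association between subtype and a demographic variable
#'
#' Builds the subtype x level contingency table of patient counts (one
#' subtype per patient by majority over that patient's samples) and runs
#' Fisher's exact test, two-sided: the exact network algorithm for tables
#' whose total is at most `exact_max`, otherwise a seeded Monte-Carlo
#' estimate with `mc_draws` draws. All-zero rows or columns are dropped
#' with a warning.
#'
#' @param assignments Named subtype labels by sample id.
#' @param clinical Clinical table.
#' @param variable One of `age_group`, `sex`, `race`.
#' @param exact_max Largest table total for the exact test (default 200).
#' @param mc_draws Monte-Carlo replicates beyond `exact_max`
#'   (default 1e5).
#' @param seed Seed for the Monte-Carlo path.
#' @return A list: `table`, `p_value`, `method`.
#' @export
demographic_association <- function(assignments, clinical,
                                    variable = c("age_group", "sex", "race"),
                                    exact_max = 200, mc_draws = 1e5,
                                    seed = 1L) {
  variable <- match.arg(variable)
  sle <- clinical[clinical$state == "SLE", , drop = FALSE]
  sle <- sle[order(sle$patient_id, sle$time_days), , drop = FALSE]
  pats <- unique(sle$patient_id)
  subtype <- character(length(pats))
  level <- character(length(pats))
  for (i in seq_along(pats)) {
    rows <- sle[sle$patient_id == pats[i], , drop = FALSE]
    labs <- assignments[rows$sample_id]
    labs <- labs[!is.na(labs)]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    subtype[i] <- if (length(top) == 1) top else labs[labs %in% top][1]
    level[i] <- rows[[variable]][1]
  }
  ct <- table(subtype, level)
  zr <- rowSums(ct) == 0
  zc <- colSums(ct) == 0
  if (any(zr) || any(zc)) {
    warn_("dropping %d empty row(s)/column(s) from contingency table",
          sum(zr) + sum(zc))
    ct <- ct[!zr, !zc, drop = FALSE]
  }
  if (nrow(ct) < 2 || ncol(ct) < 2) {
    stop_("need >= 2 subtypes and >= 2 levels of %s", variable)
  }
  if (sum(ct) <= exact_max) {
    p <- stats::fisher.test(ct)$p.value
    method <- "exact"
  } else {
    p <- withr::with_seed(seed,
      stats::fisher.test(ct, simulate.p.value = TRUE, B = mc_draws)$p.value)
    method <- sprintf("monte-carlo (B = %d)", as.integer(mc_draws))
  }
  list(table = ct, p_value = p, method = method)
}
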