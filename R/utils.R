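# Shared internal helpers.

# Days per month used to express SLEDAI change rates "per month".
DAYS_PER_MONTH <- 30.44

SUBTYPE_LEVELS <- c("mixed", "IFN-high", "NE-high")

#' @noRd
stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# Row-wise ranks with average ties; fast for small numbers of columns
# (visit counts are <= ~10 in this pipeline).
#' @noRd
row_ranks <- function(x) {
  n <- ncol(x)
  r <- matrix(1, nrow(x), n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == j) next
      r[, j] <- r[, j] + (x[, k] < x[, j]) + 0.5 * (x[, k] == x[, j])
    }
  }
  dimnames(r) <- dimnames(x)
  r
}

# Pearson correlation of every row of `x` against vector `y`.
# Rows with zero variance get correlation 0 (the pipeline's convention for
# flat genes within a patient).
#' @noRd
row_cor <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  sx <- sqrt(rowSums(xc^2))
  num <- as.vector(xc %*% yc)
  out <- numeric(nrow(x))
  ok <- sx > 0 & sy > 0
  out[ok] <- num[ok] / (sx[ok] * sy)
  out <- pmin(1, pmax(-1, out))
  names(out) <- rownames(x)
  out
}

# Row-wise one-way ANOVA F statistics for a grouping factor over columns.
# Returns f, p for each row; identical-in-both-groups rows get F = 0, p = 1,
# and rows with zero within-group variance but real between-group separation
# get F = Inf, p = 0.
#' @noRd
row_anova <- function(x, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- ncol(x)
  if (any(table(group) < 2)) {
    stop_("each group needs at least 2 samples for the ANOVA screen")
  }
  ind <- stats::model.matrix(~ 0 + group)      # n x k indicator
  cnt <- colSums(ind)
  gs <- x %*% ind                              # group sums, genes x k
  gm <- sweep(gs, 2, cnt, "/")                 # group means
  tot <- rowSums(x)
  ssb <- rowSums(sweep(gm^2, 2, cnt, "*")) - tot^2 / n
  sst <- rowSums(x^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb <= 1e-12 * pmax(sst, 1e-300)] <- 0
  f[ssw <= 1e-12 * sst & ssb > 1e-12 * sst] <- Inf
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[f == 0] <- 1
  list(f = f, p = p)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
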