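#' Summed peptide intensity for one group in one sample
#'
#' @param obs observation table.
#' @param support_peptides the group's supporting peptide sequences.
#' @param sample_id sample to sum over.
#' @param region optional gel region restriction (the resolved region).
#' @return non-negative total intensity (0 when nothing was observed).
#' @export
summed_intensity <- function(obs, support_peptides, sample_id,
                             region = NULL) {
  o <- obs[obs$sample_id == sample_id & obs$peptide %in% support_peptides, ]
  if (!is.null(region)) o <- o[o$gel_region == region, ]
  sum(o$intensity)
}

#' Fold difference with limit-of-detection substitution
#'
#' Samples in which no peptide of the protein was detected contribute an
#' intensity equal to the limit of detection, so the ratio of tissue means
#' stays defined under censoring. When one tissue had no detections at all
#' the ratio is a bound, rendered downstream with a `>` or `<` prefix.
#'
#' @param skin_sums,liver_sums per-sample summed intensities (zeros mark
#'   non-detections).
#' @param lod positive intensity used in place of zero sums.
#' @return list with `ratio` (mean substituted skin / mean substituted
#'   liver) and `bound` (`"point"`, `"lower-bound"` when liver was all
#'   zero, `"upper-bound"` when skin was all zero).
#' @export
fold_difference <- function(skin_sums, liver_sums, lod) {
  if (length(skin_sums) == 0L || length(liver_sums) == 0L)
    stop("both tissues need >= 1 sample")
  if (!is.numeric(lod) || length(lod) != 1L || is.na(lod) || lod <= 0)
    stop("configuration error: lod must be a positive intensity")
  if (any(skin_sums < 0) || any(liver_sums < 0))
    stop("summed intensities must be non-negative")
  skin <- ifelse(skin_sums == 0, lod, skin_sums)
  liver <- ifelse(liver_sums == 0, lod, liver_sums)
  bound <- if (all(liver_sums == 0) && !all(skin_sums == 0)) "lower-bound"
           else if (all(skin_sums == 0) && !all(liver_sums == 0))
             "upper-bound"
           else "point"
  list(ratio = mean(skin) / mean(liver), bound = bound)
}

#' Render a fold difference with its bound prefix
#'
#' @param ratio positive fold difference.
#' @param bound bound flag from [fold_difference()].
#' @param digits significant digits for bounds / decimals for points.
#' @return text such as `"0.10"`, `">6.7"` or `"<0.15"`.
#' @export
render_fold <- function(ratio, bound = "point", digits = 2) {
  val <- signif(ratio, digits)
  txt <- format(val, scientific = FALSE, trim = TRUE)
  switch(bound,
         point = sprintf(paste0("%.", digits, "f"), ratio),
         `lower-bound` = paste0(">", txt),
         `upper-bound` = paste0("<", txt),
         stop("unknown bound flag"))
}

#' Exact two-sided Mann-Whitney test
#'
#' For combined sample sizes up to `exact_limit` (default 25, covering the
#' 10-vs-5 tissue comparison) the two-sided p-value is computed from the
#' exact permutation distribution of the rank-sum statistic over all
#' `choose(n1+n2, n1)` group labellings, with ties handled by mid-ranks
#' (the distribution is taken over distinguishable arrangements of the
#' observed, possibly tied, ranks). The two-sided p doubles the smaller
#' one-sided tail, capped at 1. Above `exact_limit` the normal
#' approximation with tie correction and continuity correction is used.
#' Identical samples give p = 1.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @param exact_limit largest combined n for the exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p.value`, and
#'   `exact` (logical).
#' @export
mann_whitney <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            is.numeric(x), is.numeric(y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (N <= exact_limit) {
    d <- as.integer(round(2 * r))     # doubled mid-ranks are integers
    w <- as.integer(round(2 * W))
    dist <- ranksum_distribution(d, n1)
    total <- choose(N, n1)
    sums <- as.integer(names(dist))
    p_lo <- sum(dist[sums <= w]) / total
    p_hi <- sum(dist[sums >= w]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = W, p.value = 1, exact = FALSE))
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = W, p.value = p, exact = exact)
}

# exact count of subsets of size k of the doubled ranks d by sum,
# dynamic programme over items; counts fit exactly in doubles for n <= 25
ranksum_distribution <- function(d, k) {
  S <- sum(d)
  cnt <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  cnt[1L, 1L] <- 1
  for (di in d) {
    for (kk in seq.int(min(k, nrow(cnt) - 1L), 1L)) {
      shifted <- c(rep(0, di), cnt[kk, seq_len(S + 1L - di)])
      cnt[kk + 1L, ] <- cnt[kk + 1L, ] + shifted
    }
  }
  res <- cnt[k + 1L, ]
  names(res) <- 0:S
  res[res > 0]
}

#' Render a p-value for publication-style tables
#'
#' @param p p-value in (0, 1].
#' @return `"<0.001"` below 0.001, otherwise the value at 2 significant
#'   figures.
#' @export
p_display <- function(p) {
  stopifnot(p > 0, p <= 1)
  if (p < 0.001) "<0.001"
  else format(signif(p, 2), scientific = FALSE, trim = TRUE)
}

#' Distinct-peptide count profile across samples, models or timepoints
#'
#' The number of distinct tryptic peptides detected per protein group is
#' an indirect measure of relative protein quantity; profiles across
#' in-vitro models or culture timepoints are compared on that basis.
#'
#' @param support data.frame `group_id`, `peptide`.
#' @param obs_columns named list of observation tables, one per column.
#' @param rank_cor also return the pairwise Spearman rank-correlation
#'   matrix of the columns (a convenience summary).
#' @return matrix (groups x columns) of distinct-peptide counts; when
#'   `rank_cor` is TRUE, a list with `profile` and `rank_correlation`.
#' @export
peptide_count_profile <- function(support, obs_columns, rank_cor = FALSE) {
  stopifnot(is.list(obs_columns), length(obs_columns) >= 1L,
            !is.null(names(obs_columns)))
  gids <- unique(support$group_id)
  prof <- matrix(0L, nrow = length(gids), ncol = length(obs_columns),
                 dimnames = list(gids, names(obs_columns)))
  for (j in seq_along(obs_columns)) {
    o <- obs_columns[[j]]
    for (g in gids) {
      peps <- support$peptide[support$group_id == g]
      prof[g, j] <- length(unique(o$peptide[o$peptide %in% peps]))
    }
  }
  if (!rank_cor) return(prof)
  list(profile = prof,
       rank_correlation = stats::cor(prof, method = "spearman"))
}
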