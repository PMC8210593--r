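#' Extract the extreme quantile groups of a cohort
#'
#' Sorts samples in ascending order of `by` (tie-break by `sample_id`, so the
#' result is invariant under input permutation) and returns the bottom and
#' top `fraction` of samples (default the bottom 20% and the top 20%). Group
#' size is `floor(fraction * N)`.
#'
#' @param table data frame with a `sample_id` column (unique) and the numeric
#'   column `by`.
#' @param by name of the numeric column to sort by (default `"hrd"`).
#' @param fraction quantile fraction in `(0, 0.5]` (default 0.2).
#' @return List with character vectors `low` and `high` of sample ids
#'   (disjoint), each of length `floor(fraction * N)`.
#' @export
stratify_extremes <- function(table, by = "hrd", fraction = 0.2) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 0.5) {
    stop("fraction must be in (0, 0.5]")
  }
  if (!by %in% names(table)) stop("column not found: ", by)
  if (!is.numeric(table[[by]])) stop("column ", by, " must be numeric")
  if (anyDuplicated(table$sample_id)) stop("sample_id must be unique")
  n <- nrow(table)
  if (n < 5) stop("need at least 5 samples, got ", n)
  o <- order(table[[by]], table$sample_id)
  ids <- table$sample_id[o]
  n_group <- floor(fraction * n)
  list(low = ids[seq_len(n_group)],
       high = ids[seq.int(n - n_group + 1L, n)])
}

#' Classify samples as HRD-positive
#'
#' Adds (or overwrites) an `hrd_positive` column: `TRUE` when `hrd` is
#' strictly greater than `threshold` (default 26), so a score of exactly 26
#' is HRD-negative. Missing scores yield `NA` with a warning.
#'
#' @param table data frame with an `hrd` column.
#' @param threshold classification threshold (strict `>`; default 26).
#' @return `table` with an `hrd_positive` logical column.
#' @export
classify_hrd <- function(table, threshold = 26) {
  if (!"hrd" %in% names(table)) stop("table has no hrd column")
  if (nrow(table) && anyNA(table$hrd)) {
    warning("missing hrd values: flagged NA and excluded from classification")
  }
  table$hrd_positive <- table$hrd > threshold
  table
}

#' Rank-sum comparison of two independent groups
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test. For small samples
#' (`length(a) + length(b) <= exact_max`, default 12) the null distribution
#' is enumerated exactly over all group assignments of the pooled average
#' ranks; otherwise a tie-corrected normal approximation (no continuity
#' correction) is used. If every value in both groups is identical the test
#' is degenerate and `p = 1` is returned with a warning.
#'
#' The groups here are independent samples (e.g. top vs bottom HRD-score
#' quintile), so the rank-sum test -- not the paired signed-rank test -- is
#' the appropriate Wilcoxon variant.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param exact_max largest pooled size for exact enumeration.
#' @return List with `statistic` (the Mann-Whitney U for group `a`) and
#'   `p.value` (two-sided).
#' @export
compare_groups <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = na * nb / 2, p.value = 1))
  }
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  u_obs <- w_obs - na * (na + 1) / 2
  e_w <- na * (n + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, na)
    w_all <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    z <- (w_obs - e_w) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u_obs, p.value = min(p, 1))
}
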