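#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival step function per group. At tied times, events
#' precede censorings (both leave the risk set after the time point), the
#' standard convention. With no censoring the estimate equals the empirical
#' survival function.
#'
#' @param time positive follow-up times (e.g. months).
#' @param event event indicator: 1 = event observed, 0 = censored.
#' @param group optional group labels; default a single group.
#' @return Data frame with one row per distinct time per group: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  time <- unname(time); event <- unname(event); group <- unname(group)
  out <- lapply(split(seq_along(time), group), function(idx) {
    t_g <- time[idx]; e_g <- event[idx]
    u <- sort(unique(t_g))
    n <- length(t_g)
    d <- vapply(u, function(tt) sum(t_g == tt & e_g == 1), numeric(1))
    cens <- vapply(u, function(tt) sum(t_g == tt & e_g == 0), numeric(1))
    removed <- cumsum(d + cens)
    n_risk <- n - c(0, removed[-length(removed)])
    surv <- cumprod(1 - d / n_risk)
    data.frame(group = group[idx[1]], time = u, n_risk = n_risk,
               n_event = d, n_censor = cens, surv = surv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square over shared event times for two
#' or more groups, with `df = k - 1`. The statistic is
#' `(O - E)' V^{-1} (O - E)` over the first `k - 1` groups, with the usual
#' hypergeometric variance-covariance at each event time.
#'
#' @inheritParams km_estimate
#' @param group group labels, at least two distinct values.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- as.character(group)
  labs <- sort(unique(group))
  k <- length(labs)
  if (k < 2) stop("need at least 2 groups")
  if (sum(event) == 0) stop("no events observed")
  gidx <- match(group, labs)
  event_times <- sort(unique(time[event == 1]))
  omE <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (tt in event_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    d <- sum(event == 1 & time == tt)
    if (n <= 1 || d == 0) next
    nj <- vapply(seq_len(k), function(j) sum(at_risk & gidx == j), numeric(1))
    dj <- vapply(seq_len(k), function(j) {
      sum(event == 1 & time == tt & gidx == j)
    }, numeric(1))
    ej <- d * nj / n
    omE <- omE + (dj - ej)[seq_len(k - 1)]
    cfac <- d * (n - d) / (n - 1)
    for (a in seq_len(k - 1)) {
      for (b in seq_len(k - 1)) {
        V[a, b] <- V[a, b] +
          cfac * (nj[a] / n) * ((a == b) - nj[b] / n)
      }
    }
  }
  Vinv <- tryCatch(solve(V), error = function(e) {
    sv <- svd(V)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  })
  stat <- drop(t(omE) %*% Vinv %*% omE)
  list(statistic = stat, df = k - 1,
       p.value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Split samples into expression-high and expression-low groups
#'
#' Default rule is a median split: values strictly above the median are
#' "high", so with odd `n` the median value itself lands in the low group.
#' The optional `"best"` rule scans inner quantile cut points for the one
#' maximising the log-rank statistic against supplied survival data; this
#' optimises the split on the same data it will be tested on, so the
#' resulting p-value is optimistic (a warning says so).
#'
#' @param values numeric expression values (not all equal).
#' @param rule `"median"` (default) or `"best"`.
#' @param time,event survival data, required for `rule = "best"`.
#' @param probs candidate quantiles scanned in best-cutoff mode.
#' @return Factor with levels `low`, `high`, same length as `values`.
#' @export
split_by_expression <- function(values, rule = c("median", "best"),
                                time = NULL, event = NULL,
                                probs = seq(0.2, 0.8, by = 0.05)) {
  rule <- match.arg(rule)
  if (length(unique(values)) == 1L) {
    stop("all expression values equal; cannot split")
  }
  if (rule == "median") {
    cut <- stats::median(values)
  } else {
    if (is.null(time) || is.null(event)) {
      stop("best-cutoff mode needs time and event")
    }
    warning("best-cutoff split optimises the log-rank statistic on the ",
            "same data; downstream p-values are optimistic")
    cands <- unique(stats::quantile(values, probs, type = 1))
    best <- -Inf; cut <- NA
    for (cc in cands) {
      lab <- values > cc
      if (!any(lab) || all(lab)) next
      st <- logrank_test(time, event, ifelse(lab, "high", "low"))$statistic
      if (st > best) { best <- st; cut <- cc }
    }
    if (is.na(cut)) stop("no admissible cut point found")
  }
  factor(ifelse(values > cut, "high", "low"), levels = c("low", "high"))
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all score thresholds with the trapezoid-rule AUC,
#' which equals the Mann-Whitney U statistic divided by `n1 * n0` with tied
#' score pairs counted one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param outcome binary outcome (0/1 or logical); both classes must be
#'   present.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2) {
    stop("outcome must be binary with both classes present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & outcome == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & outcome == 0) / n0,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Pearson or Spearman correlation with t-approximation p-value
#'
#' Spearman uses average ranks for ties. The p-value comes from the usual
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom (for Spearman this is the standard large-sample approximation).
#' Zero variance in either vector yields an `NA` estimate with
#' `degenerate = TRUE` and a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row data frame: `method`, `estimate`, `n`, `p.value`,
#'   `degenerate`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(data.frame(method = method, estimate = NA_real_, n = n,
                      p.value = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(method = method, estimate = r, n = n, p.value = p,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. This matches the common convention (and
#' `fisher.test`); the alternative "doubling" definition is not used.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    stop("entries must be non-negative integers")
  }
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  min(sum(dens[dens <= obs * (1 + 1e-7)]), 1)
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H statistic with the chi-square approximation,
#' `df = k - 1`. If every value is identical the statistic is degenerate and
#' `p = 1` is returned with a warning.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("groups must be non-empty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  if (length(unique(x)) == 1L) {
    warning("all values identical; p = 1")
    return(list(statistic = 0, df = length(groups) - 1, p.value = 1))
  }
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / cf
  df <- length(groups) - 1
  list(statistic = h, df = df,
       p.value = stats::pchisq(h, df, lower.tail = FALSE))
}
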