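test_that("km_estimate reproduces hand product-limit results", {
  # no events: S(t) = 1 everywhere
  km <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # three events: 2/3, 1/3, 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km2$n_risk, c(3, 2, 1))
  # single censored subject
  km3 <- km_estimate(5, 0)
  expect_equal(km3$surv, 1)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("km_estimate matches survival::survfit, ties included", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    time <- sample(1:15, n, replace = TRUE)  # force ties
    event <- stats::rbinom(n, 1, 0.7)
    if (!sum(event)) event[1] <- 1
    km <- km_estimate(time, event)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    at <- match(km$time, fit$time)
    expect_equal(km$surv, fit$surv[at], tolerance = 1e-12)
    expect_equal(km$n_risk, fit$n.risk[at])
    expect_equal(km$n_event, fit$n.event[at])
  }
})

test_that("km with no censoring equals the empirical survival function", {
  set.seed(32)
  time <- stats::rexp(50) + 0.1
  km <- km_estimate(time, rep(1, 50))
  ecdf_surv <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("logrank_test reproduces a hand-computed two-group example", {
  # groups A: events at 1, 3; B: event at 2, censored at 4
  time <- c(1, 3, 2, 4)
  event <- c(1, 1, 1, 0)
  group <- c("A", "A", "B", "B")
  # hand computation over event times 1, 2, 3:
  # t=1: nA=2,nB=2,d=1 -> eA=1/2, v=(1*3/3)*(2/4)*(2/4)=1/4
  # t=2: nA=1,nB=2,d=1 -> eA=1/3, v=(1*2/2)*(1/3)*(2/3)=2/9
  # t=3: nA=1,nB=1,d=1 -> eA=1/2, v=(1*1/1)*(1/2)*(1/2)=1/4
  oA <- 2; eA <- 1 / 2 + 1 / 3 + 1 / 2; v <- 1 / 4 + 2 / 9 + 1 / 4
  want <- (oA - eA)^2 / v
  got <- logrank_test(time, event, group)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p.value, stats::pchisq(want, 1, lower.tail = FALSE))
})

test_that("identical duplicated groups give statistic 0, p = 1", {
  time <- rep(c(1, 2, 3), 2)
  event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)
  got <- logrank_test(time, event, group)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p.value, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "2 groups")
})

test_that("logrank_test matches survival::survdiff for 2 and 3 groups", {
  set.seed(33)
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    n <- sample(20:60, 1)
    group <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(group)) < k) next
    time <- sample(1:20, n, replace = TRUE)
    event <- stats::rbinom(n, 1, 0.7)
    if (!sum(event)) event[1] <- 1
    got <- logrank_test(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(got$statistic, unname(ref$chisq), tolerance = 1e-9)
    expect_equal(got$df, k - 1)
  }
})

test_that("logrank statistic is invariant under monotone time transforms", {
  set.seed(34)
  time <- stats::rexp(60) + 0.5
  event <- stats::rbinom(60, 1, 0.8)
  group <- rep(c("A", "B"), 30)
  a <- logrank_test(time, event, group)
  b <- logrank_test(log(time + 1), event, group)
  cc <- logrank_test(time^2, event, group)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$statistic, cc$statistic, tolerance = 1e-12)
})

test_that("split_by_expression median rule puts the median in low", {
  s <- split_by_expression(1:10)
  expect_equal(sum(s == "high"), 5L)
  s2 <- split_by_expression(1:9)
  expect_equal(as.character(s2[5]), "low")  # median value -> low group
  expect_equal(sum(s2 == "high"), 4L)
  expect_error(split_by_expression(rep(3, 6)), "all expression values equal")
})

test_that("best-cutoff split recovers a generative boundary approximately", {
  set.seed(35)
  hit <- 0L
  for (rep in 1:10) {
    n <- 200
    risk <- rep(c(0, 1), each = n / 2)          # true boundary at median
    expr <- 5 + 3 * risk + stats::rnorm(n, 0, 0.5)
    time <- stats::rexp(n, 0.05 * exp(-1.5 * risk))
    suppressWarnings(
      s <- split_by_expression(expr, rule = "best", time = time,
                               event = rep(1, n)))
    frac_high <- mean(s == "high")
    if (abs(frac_high - 0.5) <= 0.1) hit <- hit + 1L
  }
  expect_gte(hit, 9L)
})

test_that("roc_auc equals the Mann-Whitney identity and its reflection", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # random scores at large n hover near 1/2
  set.seed(36)
  big <- roc_auc(stats::rnorm(4000), stats::rbinom(4000, 1, 0.5))
  expect_lt(abs(big$auc - 0.5), 0.05)
  # trapezoid AUC == U/(n1 n0) with ties counted half, and AUC reflection
  for (rep in 1:30) {
    n <- sample(8:40, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    outcome <- stats::rbinom(n, 1, 0.5)
    if (length(unique(outcome)) < 2) next
    r <- roc_auc(scores, outcome)
    s1 <- scores[outcome == 1]; s0 <- scores[outcome == 0]
    u <- sum(vapply(s1, function(x) {
      sum(x > s0) + 0.5 * sum(x == s0)
    }, numeric(1)))
    expect_equal(r$auc, u / (length(s1) * length(s0)), tolerance = 1e-12)
    expect_equal(r$auc + roc_auc(-scores, outcome)$auc, 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("correlate handles the exact and degenerate cases", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$estimate, 1)
  expect_equal(correlate(x, exp(x), method = "spearman")$estimate, 1)
  expect_warning(out <- correlate(x, rep(2, 10)), "zero variance")
  expect_true(out$degenerate)
  expect_error(correlate(1:3, 1:4), "equal length")
})

test_that("correlate matches brute-force formulas and cor.test", {
  set.seed(37)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties for spearman averaging
    y <- sample(1:10, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ps <- correlate(x, y, "pearson")
    sp <- correlate(x, y, "spearman")
    # brute-force pearson
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ps$estimate, r_brute, tolerance = 1e-12)
    # spearman as pearson of average ranks
    expect_equal(sp$estimate,
                 stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(ps$p.value,
                 stats::cor.test(x, y)$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_exact_2x2 uses the probability-mass two-sided rule", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  # identical row proportions
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 6, 6), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  set.seed(38)
  for (rep in 1:50) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("kruskal_wallis reproduces the tie-corrected H", {
  # identical groups: H = 0
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0,
               tolerance = 1e-12)
  expect_warning(deg <- kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_equal(deg$p.value, 1)
  # hand-computable 3-group toy, no ties:
  # groups {1,2}, {3,4}, {5,6}: rank sums 3, 7, 11; N = 6
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 4.571428...
  got <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(got$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(got$df, 2)
  set.seed(39)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) sample(1:8, sample(3:10, 1),
                                                    replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    ref <- stats::kruskal.test(groups)
    got <- kruskal_wallis(groups)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("k = 2 kruskal-wallis approaches the rank-sum normal test", {
  set.seed(40)
  diffs <- replicate(40, {
    a <- stats::rnorm(60); b <- stats::rnorm(60, 0.3)
    kw <- kruskal_wallis(list(a, b))$p.value
    rs <- compare_groups(a, b)$p.value
    abs(kw - rs)
  })
  # chi-square(1) of z^2 equals the two-sided normal p exactly;
  # the two tests differ only in tie handling details here
  expect_lt(stats::median(diffs), 1e-10)
})
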