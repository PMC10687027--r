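test_that("Kaplan-Meier product-limit handles events, censoring, edge cases", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km_surv_at(km, c(0.5, 1, 1.5, 2)), c(1, 0.5, 0.5, 0))

  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))      # all censored
  expect_true(all(km2$surv == 1))

  km3 <- km_estimate(c(1, 2), c(1, 0))            # event then censoring
  expect_equal(km_surv_at(km3, 1), 0.5)
  expect_gt(min(km3$surv), 0)                     # never reaches zero

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank is null on identical groups and matches exact permutation", {
  g <- list(times = c(1, 2, 3, 4), events = c(1, 1, 0, 1))
  res <- logrank_test(list(g, g))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  res4 <- logrank_test(list(g, g, g, g))          # k identical groups
  expect_equal(res4$p, 1, tolerance = 1e-10)
  expect_equal(res4$df, 3)
  expect_error(logrank_test(list(g)), "at least 2")

  # exact permutation null on a 4-observation case: enumerate all label
  # splits and compare the permutation p with the chi-square approximation
  times <- c(1, 2, 3, 4); events <- rep(1, 4)
  obs <- logrank_test(times = times, events = events,
                      labels = c(1, 1, 2, 2))$chisq
  splits <- utils::combn(4, 2, simplify = FALSE)
  null_stats <- vapply(splits, function(ix) {
    lab <- rep(2, 4); lab[ix] <- 1
    logrank_test(times = times, events = events, labels = lab)$chisq
  }, numeric(1))
  p_exact <- mean(null_stats >= obs - 1e-12)
  expect_equal(p_exact, 1 / 3)                    # the split and its mirror
  # the observed split is the most extreme configuration
  expect_equal(max(null_stats), obs, tolerance = 1e-12)
})

test_that("log-rank detects a planted hazard ratio of 3", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    t1 <- stats::rexp(100, 1); t2 <- stats::rexp(100, 3)
    cens <- stats::runif(200, 0, 5)
    tt <- pmin(c(t1, t2), cens); ev <- as.integer(c(t1, t2) <= cens)
    logrank_test(times = tt, events = ev,
                 labels = rep(1:2, each = 100))$p < 0.01
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("BH adjustment matches the step-up formula and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(51)
  for (rep in 1:5) {
    p <- stats::runif(40)
    q <- bh_fdr(p)
    # direct step-up: q_i = min_{j: p_j >= p_i} p_j * m / rank_j
    m <- length(p)
    o <- order(p)
    direct <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
    expect_equal(q, direct, tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    perm <- sample(m)
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("Cox recovers a planted log-hazard and keeps the sign convention", {
  est <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 300
    x <- stats::rnorm(n)
    tt <- stats::rexp(n, rate = 0.3 * exp(0.7 * x))
    cens <- stats::runif(n, 0, 12)
    X <- matrix(x, n, 1, dimnames = list(sprintf("s%03d", 1:n), "g1"))
    clin <- clinical_table(data.frame(sample = rownames(X),
                                      pfs_time = pmin(tt, cens),
                                      event = as.integer(tt <= cens)))
    cox_fit(X, clin, scale_covariates = FALSE)$coef
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.15)
  expect_true(all(est > 0))                       # detrimental => HR > 1
})

test_that("Cox univariate mode flags degenerate covariates, dedups consistently", {
  set.seed(52)
  n <- 120
  x <- stats::rnorm(n)
  tt <- stats::rexp(n, exp(0.5 * x))
  X <- cbind(g1 = x, g2 = x, flat = rep(1, n))
  rownames(X) <- sprintf("s%03d", 1:n)
  clin <- clinical_table(data.frame(sample = rownames(X), pfs_time = tt,
                                    event = 1))
  res <- cox_fit(X, clin)
  expect_equal(res$coef[res$covariate == "g1"],
               res$coef[res$covariate == "g2"])   # duplicated gene
  expect_equal(res$flag[res$covariate == "flat"], "constant")
  expect_true(is.na(res$q[res$covariate == "flat"]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_equal(res$hr, exp(res$coef), tolerance = 1e-12)
})

test_that("multivariable Cox fits jointly and drops constants with a warning", {
  set.seed(53)
  n <- 150
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  tt <- stats::rexp(n, exp(0.6 * x1 - 0.4 * x2))
  X <- cbind(a = x1, b = x2, flat = 0)
  rownames(X) <- sprintf("s%03d", 1:n)
  clin <- clinical_table(data.frame(sample = rownames(X), pfs_time = tt,
                                    event = 1))
  expect_warning(res <- cox_fit(X, clin, mode = "multivariable"), "constant")
  expect_equal(nrow(res), 2)
  expect_gt(res$coef[res$covariate == "a"], 0)
  expect_lt(res$coef[res$covariate == "b"], 0)
})
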