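# Censored-normal MLE, truncated sampling, tobit regression, TOST.

test_that("censored fit with no censoring reduces to the closed-form MLE", {
  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(40, 30, 2)
    fit <- fit_censored_normal(y, rep(FALSE, 40), limit = 100)
    expect_equal(fit$mu, mean(y), tolerance = 1e-6)
    expect_equal(fit$sigma, sqrt(sum((y - mean(y))^2) / 40), tolerance = 1e-6)
    expect_true(fit$converged)
    expect_equal(fit$n_obs, 40L)
    expect_equal(fit$n_cens, 0L)
  }
})

test_that("censored fit recovers generating parameters and beats a grid search", {
  set.seed(21)
  y <- rnorm(10000, 35, 2)
  cens <- y > 40
  fit <- fit_censored_normal(ifelse(cens, NA, y), cens, limit = 40)
  expect_lt(abs(fit$mu - 35), 0.05)
  expect_lt(abs(fit$sigma - 2), 0.05)

  # independent oracle: grid maximizer of the same likelihood on a small set
  y2 <- rnorm(300, 38, 1.5)
  cens2 <- y2 > 40
  obs2 <- y2[!cens2]
  ll <- function(mu, s)
    sum(dnorm(obs2, mu, s, log = TRUE)) +
      sum(cens2) * pnorm(40, mu, s, lower.tail = FALSE, log.p = TRUE)
  mus <- seq(36, 40, by = 0.005)
  sigs <- seq(0.8, 2.5, by = 0.005)
  grid <- outer(mus, sigs, Vectorize(ll))
  best <- arrayInd(which.max(grid), dim(grid))
  fit2 <- fit_censored_normal(ifelse(cens2, NA, y2), cens2, limit = 40)
  expect_lt(abs(fit2$mu - mus[best[1]]), 0.005 + 1e-9)
  expect_lt(abs(fit2$sigma - sigs[best[2]]), 0.005 + 1e-9)
  expect_gte(fit2$loglik, max(grid) - 1e-9)
})

test_that("censored fit is shift-equivariant", {
  set.seed(31)
  y <- rnorm(200, 38, 1.5)
  cens <- y > 40
  f0 <- fit_censored_normal(ifelse(cens, NA, y), cens, limit = 40)
  f1 <- fit_censored_normal(ifelse(cens, NA, y + 5), cens, limit = 45)
  expect_equal(f1$mu, f0$mu + 5, tolerance = 1e-6)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-6)
})

test_that("censored log-likelihood is locally maximal at the fit", {
  set.seed(41)
  for (i in 1:10) {
    mu <- runif(1, 34, 39); s <- runif(1, 0.8, 2.5)
    y <- rnorm(150, mu, s)
    cens <- y > 40
    if (sum(!cens) < 5) next
    fit <- fit_censored_normal(ifelse(cens, NA, y), cens, limit = 40)
    ll <- function(mu, s)
      sum(dnorm(y[!cens], mu, s, log = TRUE)) +
        sum(cens) * pnorm(40, mu, s, lower.tail = FALSE, log.p = TRUE)
    for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05)))
      expect_lt(ll(fit$mu + d[1], fit$sigma + d[2]), fit$loglik)
  }
})

test_that("bias of the censored mean estimate shrinks with sample size", {
  set.seed(51)
  bias_at <- function(n, reps = 250) {
    mean(replicate(reps, {
      y <- rnorm(n, 39, 2)  # ~31% censored at 40
      cens <- y > 40
      if (sum(!cens) < 3) return(NA_real_)
      fit_censored_normal(ifelse(cens, NA, y), cens, 40)$mu - 39
    }), na.rm = TRUE)
  }
  b50 <- bias_at(50); b5000 <- bias_at(5000, reps = 60)
  expect_lt(abs(b5000), abs(b50) + 0.005)
  expect_lt(abs(b5000), 0.02)
})

test_that("all-censored and degenerate inputs are rejected", {
  expect_error(fit_censored_normal(rep(NA_real_, 5), rep(TRUE, 5), 40),
               "censored")
  expect_error(fit_censored_normal(c(30, NA), c(FALSE, TRUE), 40),
               "at least 2")
  expect_error(fit_censored_normal(rep(30, 5), rep(FALSE, 5), 40),
               "degenerate")
})

test_that("truncated-normal draws respect the support and the analytic mean", {
  x <- sample_truncated_normal(1e5, 35, 2, lower = 40, seed = 7)
  expect_true(all(x >= 40))
  a <- (40 - 35) / 2
  m_true <- 35 + 2 * dnorm(a) / pnorm(a, lower.tail = FALSE)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m_true), 3 * se)

  # no truncation limit recovers the plain normal
  y <- sample_truncated_normal(1e5, 10, 3, lower = -Inf, seed = 8)
  expect_lt(abs(mean(y) - 10), 3 * 3 / sqrt(1e5))
  expect_lt(abs(sd(y) - 3), 0.05)

  # extreme tail: inverse-CDF method stays finite and in support
  z <- sample_truncated_normal(100, 0, 1, lower = 12, seed = 9)
  expect_true(all(is.finite(z)) && all(z >= 12))
})

test_that("tobit with no censoring equals the group-mean difference", {
  set.seed(61)
  for (i in 1:10) {
    y <- rnorm(60, 20, 2) + rep(c(0, 1.5), each = 30) * runif(1, -2, 2)
    g <- rep(c(0, 1), each = 30)
    fit <- tobit_two_group(y, rep(FALSE, 60), g, limit = Inf)
    expect_equal(fit$beta1, mean(y[g == 1]) - mean(y[g == 0]),
                 tolerance = 1e-6)
    # Wald p equals the pooled z-test built from the same MLE variance
    s <- fit$sigma
    se <- s * sqrt(1 / 30 + 1 / 30)
    p_z <- 2 * pnorm(-abs(fit$beta1 / se))
    expect_equal(fit$p_value, p_z, tolerance = 1e-6)
  }
})

test_that("tobit agrees with survreg on censored data", {
  skip_if_not_installed("survival")
  set.seed(71)
  for (i in 1:5) {
    n <- 120
    g <- rep(c(0, 1), each = n / 2)
    ystar <- 37 + 1.2 * g + rnorm(n, 0, 2)
    cens <- ystar > 40
    y <- ifelse(cens, 40, ystar)
    fit <- tobit_two_group(ifelse(cens, NA, ystar), cens, g, limit = 40)
    sv <- survival::survreg(survival::Surv(y, !cens, type = "right") ~ g,
                            dist = "gaussian")
    expect_equal(fit$beta1, unname(coef(sv)[2]), tolerance = 1e-4)
    expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
    p_sv <- summary(sv)$table["g", "p"]
    expect_equal(fit$p_value, p_sv, tolerance = 1e-3)
  }
})

test_that("tobit on identical groups reports a null effect", {
  set.seed(81)
  v <- rnorm(30, 30, 1)
  y <- c(v, v)
  fit <- tobit_two_group(y, rep(FALSE, 60), rep(c(0, 1), each = 30),
                         limit = Inf)
  expect_lt(abs(fit$beta1), 1e-6)
  expect_gt(fit$p_value, 0.999)
})

test_that("tobit rejects a completely censored group", {
  y <- c(rnorm(10, 30, 1), rep(NA, 10))
  expect_error(
    tobit_two_group(y, rep(c(FALSE, TRUE), each = 10),
                    rep(c(0, 1), each = 10), limit = 40),
    "completely censored")
})

test_that("TOST declares equivalence when it should", {
  set.seed(91)
  a <- rnorm(500, 0, 1); b <- rnorm(500, 0, 1)
  r <- tost_two_group(a, b, margin = 0.5)
  expect_true(r$equivalent)
  expect_identical(r$p_tost, max(r$p_lower, r$p_upper))

  # vacuous equivalence for an enormous margin
  r2 <- tost_two_group(rnorm(20, 5), rnorm(20, 0), margin = 100)
  expect_true(r2$equivalent)

  # clearly different groups are not equivalent
  r3 <- tost_two_group(rnorm(100, 2), rnorm(100, 0), margin = 0.5)
  expect_false(r3$equivalent)

  # degenerate variance: equal constants are equivalent, unequal error
  expect_true(tost_two_group(rep(1, 5), rep(1, 5), margin = 0.5)$equivalent)
  expect_error(tost_two_group(rep(1, 5), rep(3, 5), margin = 0.5),
               "degenerate")
})
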