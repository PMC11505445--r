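# Core likelihood machinery for right-censored normal (Cq) data.
#
# A non-detect is a reaction whose true Cq exceeds the detection limit L, so
# its likelihood contribution is the upper-tail mass 1 - Phi((L - mu)/sigma).
# All optimizations run in (location, log sigma) with analytic gradients,
# deterministic initialization at uncensored sample moments, and a Newton
# polish until the gradient norm is below tolerance, so fits are reproducible
# and (for the uncensored special case) agree with closed-form MLEs to high
# precision.

# hazard of the standard normal: phi(a) / (1 - Phi(a)), computed in log space
# so it stays finite far into the upper tail
norm_hazard <- function(a) {
  exp(stats::dnorm(a, log = TRUE) -
        stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# Newton refinement of an optim() solution; fn/gr in the same parametrization.
newton_polish <- function(theta, fn, gr, tol = 1e-9, max_iter = 40) {
  for (it in seq_len(max_iter)) {
    g <- gr(theta)
    if (!all(is.finite(g)) || sqrt(sum(g^2)) < tol) break
    H <- stats::optimHess(theta, fn, gr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    f0 <- fn(theta)
    cand <- theta - step
    k <- 0
    while ((!is.finite(fn(cand)) || fn(cand) > f0 + 1e-12) && k < 12) {
      step <- step / 2
      cand <- theta - step
      k <- k + 1
    }
    if (!is.finite(fn(cand)) || fn(cand) > f0 + 1e-12) break
    theta <- cand
  }
  theta
}

#' Censored-normal maximum likelihood
#'
#' Fits mean and standard deviation of a normal distribution from data
#' right-censored at a known detection limit, by maximizing
#' \deqn{\sum_{obs} \log \phi((y_i-\mu)/\sigma)/\sigma +
#'       n_{cens} \log\{1 - \Phi((L-\mu)/\sigma)\}.}
#' With no censored observations this reduces to the ordinary MLE
#' (\eqn{\hat\mu} = sample mean, \eqn{\hat\sigma^2} = 1/n sum of squares).
#'
#' @param values numeric vector; entries at censored positions are ignored
#'   (may be `NA`).
#' @param censored logical vector of the same length; `TRUE` marks a
#'   censored (non-detect) observation.
#' @param limit detection limit L (finite).
#' @return list of class `censored_fit` with elements `mu`, `sigma`, `n_obs`,
#'   `n_cens`, `loglik`, `converged`.
#' @export
fit_censored_normal <- function(values, censored = rep(FALSE, length(values)),
                                limit = 40) {
  stopifnot(length(censored) == length(values), is.finite(limit))
  obs <- values[!censored]
  if (anyNA(obs)) stop("NA among uncensored values")
  n_cens <- sum(censored)
  n_obs <- length(obs)
  if (n_obs == 0) stop("all values censored: parameters not identifiable")
  if (n_obs < 2) stop("need at least 2 uncensored values")
  if (n_cens == 0 && stats::var(obs) == 0)
    stop("degenerate fit: zero variance and no censoring (sigma -> 0)")

  fn <- function(th) {
    mu <- th[1]; s <- exp(th[2])
    ll <- sum(stats::dnorm(obs, mu, s, log = TRUE))
    if (n_cens > 0)
      ll <- ll + n_cens * stats::pnorm(limit, mu, s,
                                       lower.tail = FALSE, log.p = TRUE)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  gr <- function(th) {
    mu <- th[1]; s <- exp(th[2])
    r <- (obs - mu) / s
    dmu <- sum(r) / s
    dls <- sum(r^2 - 1)
    if (n_cens > 0) {
      a <- (limit - mu) / s
      h <- norm_hazard(a)
      dmu <- dmu + n_cens * h / s
      dls <- dls + n_cens * h * a
    }
    -c(dmu, dls)
  }

  s0 <- sqrt(sum((obs - mean(obs))^2) / n_obs)
  s0 <- max(s0, 1e-3)
  th0 <- c(mean(obs), log(s0))
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  th <- newton_polish(opt$par, fn, gr)
  g <- gr(th)
  sigma <- exp(th[2])
  if (sigma < 1e-6)
    stop(sprintf("degenerate censored fit: sigma -> 0 (mu = %.3f)", th[1]))
  structure(list(mu = th[1], sigma = sigma, n_obs = n_obs, n_cens = n_cens,
                 loglik = -fn(th),
                 converged = all(is.finite(g)) && sqrt(sum(g^2)) < 1e-6),
            class = "censored_fit")
}

#' Sample from a lower-truncated normal distribution
#'
#' Draws from N(mu, sigma^2) conditioned on the value being at least `lower`,
#' by inverse-CDF transform of the upper-tail probability (computed in log
#' space, so the method stays exact arbitrarily far into the tail; there is no
#' rejection loop).
#'
#' @param n number of draws
#' @param mu,sigma normal parameters (`sigma > 0`)
#' @param lower truncation point; `-Inf` recovers the untruncated normal
#' @param seed optional integer seed (calls `set.seed`)
#' @return numeric vector of `n` draws, all `>= lower`
#' @export
sample_truncated_normal <- function(n, mu, sigma, lower, seed = NULL) {
  stopifnot(sigma > 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  # log of P(X >= lower); 0 when lower = -Inf
  log_tail <- stats::pnorm(lower, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  u <- stats::runif(n)
  stats::qnorm(log(u) + log_tail, mean = mu, sd = sigma,
               lower.tail = FALSE, log.p = TRUE)
}

#' Two-group tobit (censored Gaussian) regression
#'
#' Maximum-likelihood fit of \eqn{y^*_i = \beta_0 + \beta_1 g_i + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}, where \eqn{y^*_i} is observed when it
#' is below a (possibly per-observation) right-censoring limit and otherwise
#' only known to exceed it. \eqn{\beta_1} is the group effect on the Cq scale
#' (the \eqn{\Delta\Delta Ct} when y is reference-normalized); the p-value is
#' a two-sided Wald test of \eqn{\beta_1 = 0} using the observed information.
#'
#' @param y numeric response; entries at censored positions may be `NA`.
#' @param censored logical; `TRUE` marks right-censored observations.
#' @param group 0/1 (or logical/two-level factor) group indicator; the level
#'   coded 1 is the case group.
#' @param limit scalar or per-observation censoring limit(s).
#' @return list of class `tobit_fit`: `beta0`, `beta1`, `sigma`, `se_beta1`,
#'   `p_value`, `loglik`, `converged`, `n_obs`, `n_cens`.
#' @export
tobit_two_group <- function(y, censored = rep(FALSE, length(y)), group,
                            limit = 40) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  g <- as.numeric(group)
  stopifnot(length(g) == length(y), length(censored) == length(y),
            all(g %in% c(0, 1)))
  if (length(limit) == 1) limit <- rep(limit, length(y))
  stopifnot(length(limit) == length(y))
  for (lv in c(0, 1)) {
    n_unc <- sum(g == lv & !censored)
    if (n_unc == 0)
      stop(sprintf("group coded %d is completely censored", lv))
    if (n_unc < 2)
      stop(sprintf("group coded %d has fewer than 2 uncensored observations", lv))
  }
  obs <- !censored
  yo <- y[obs]; go <- g[obs]
  if (anyNA(yo)) stop("NA among uncensored responses")
  gc_ <- g[!obs]; Lc <- limit[!obs]
  n_cens <- sum(!obs)

  fn <- function(th) {
    b0 <- th[1]; b1 <- th[2]; s <- exp(th[3])
    ll <- sum(stats::dnorm(yo, b0 + b1 * go, s, log = TRUE))
    if (n_cens > 0)
      ll <- ll + sum(stats::pnorm(Lc, b0 + b1 * gc_, s,
                                  lower.tail = FALSE, log.p = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  gr <- function(th) {
    b0 <- th[1]; b1 <- th[2]; s <- exp(th[3])
    r <- (yo - b0 - b1 * go) / s
    d0 <- sum(r) / s
    d1 <- sum(r * go) / s
    dls <- sum(r^2 - 1)
    if (n_cens > 0) {
      a <- (Lc - b0 - b1 * gc_) / s
      h <- norm_hazard(a)
      d0 <- d0 + sum(h) / s
      d1 <- d1 + sum(h * gc_) / s
      dls <- dls + sum(h * a)
    }
    -c(d0, d1, dls)
  }

  m0 <- mean(yo[go == 0]); m1 <- mean(yo[go == 1])
  sp <- stats::sd(c(yo[go == 0] - m0, yo[go == 1] - m1))
  sp <- max(sp, 1e-3)
  starts <- list(c(m0, m1 - m0, log(sp)),
                 c(mean(yo), 0, log(sp)),
                 c(m0, m1 - m0, log(2 * sp)))
  best <- NULL
  for (th0 in starts) {
    opt <- stats::optim(th0, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    th <- newton_polish(opt$par, fn, gr)
    if (is.null(best) || fn(th) < fn(best)) best <- th
    if (sqrt(sum(gr(best)^2)) < 1e-6) break  # converged; no restart needed
  }
  th <- best
  gnorm <- sqrt(sum(gr(th)^2))
  H <- stats::optimHess(th, fn, gr)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  se1 <- sqrt(vc[2, 2])
  z <- th[2] / se1
  structure(list(beta0 = th[1], beta1 = th[2], sigma = exp(th[3]),
                 se_beta1 = se1,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = -fn(th),
                 converged = is.finite(gnorm) && gnorm < 1e-5 && is.finite(se1),
                 n_obs = sum(obs), n_cens = n_cens),
            class = "tobit_fit")
}

#' Two one-sided tests (TOST) of equivalence between two groups
#'
#' Welch two-sample one-sided t-tests of H0: difference <= -margin and
#' H0: difference >= +margin. Equivalence is declared when both are rejected,
#' i.e. when `p_tost = max(p_lower, p_upper) < alpha`.
#'
#' @param a,b numeric samples (at least 2 values each)
#' @param margin equivalence margin (delta, in Cq units, > 0)
#' @param alpha significance level for the equivalence call
#' @return list of class `tost_result`: `estimate` (mean(a) - mean(b)),
#'   `margin`, `p_lower`, `p_upper`, `p_tost`, `equivalent`, `df`.
#' @export
tost_two_group <- function(a, b, margin = 0.5, alpha = 0.05) {
  stopifnot(margin > 0, length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (abs(d) < margin)
      return(structure(list(estimate = d, margin = margin, p_lower = 0,
                            p_upper = 0, p_tost = 0, equivalent = TRUE,
                            df = Inf), class = "tost_result"))
    stop("degenerate TOST: both groups have zero variance and unequal means")
  }
  na <- length(a); nb <- length(b)
  se <- sqrt(va / na + vb / nb)
  df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p_lower <- stats::pt((d + margin) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((d - margin) / se, df, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  structure(list(estimate = d, margin = margin, p_lower = p_lower,
                 p_upper = p_upper, p_tost = p_tost,
                 equivalent = p_tost < alpha, df = df),
            class = "tost_result")
}
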