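# Imputation, the four stability algorithms, rank aggregation, selection.

test_that("imputation leaves complete matrices untouched and fills the rest", {
  v <- named_matrix(rnorm(6 * 20, 30), 6, sprefix = "C")
  colnames(v) <- c(paste0("C", 1:10), paste0("O", 1:10))
  ct <- toy_ct(v)
  sam <- toy_samples(ct)
  imp <- impute_censored(ct, sam, seed = 1)
  expect_identical(imp$values, v)

  # censored cells are filled at or beyond the limit, observed cells kept
  set.seed(2)
  v2 <- named_matrix(rnorm(4 * 40, 38.5, 1.5), 4, sprefix = "C")
  colnames(v2) <- c(paste0("C", 1:20), paste0("O", 1:20))
  v2[v2 > 40] <- NA
  ct2 <- toy_ct(v2)
  imp2 <- impute_censored(ct2, toy_samples(ct2), seed = 3)
  cens <- is.na(v2)
  expect_true(all(imp2$values[cens] >= 40))
  expect_identical(imp2$values[!cens], v2[!cens])
})

test_that("imputed non-detects follow the fitted truncated-normal mean", {
  set.seed(4)
  n <- 1500  # one target, many samples per arm, heavy censoring
  v <- named_matrix(rbind(rnorm(n, 38.5, 1.5), rnorm(n, 25, 1)), 2,
                    sprefix = "C")
  colnames(v) <- c(paste0("C", 1:(n / 2)), paste0("O", 1:(n / 2)))
  v[v > 40] <- NA
  ct <- toy_ct(v)
  imp <- impute_censored(ct, toy_samples(ct), seed = 5)
  for (g in c("CNT", "END")) {
    fit <- imp$fits[["t1"]][[if (g == "CNT") "CNT" else "END"]]
    a <- (40 - fit$mu) / fit$sigma
    m_true <- fit$mu + fit$sigma * dnorm(a) / pnorm(a, lower.tail = FALSE)
    cols <- if (g == "CNT") grepl("^C", colnames(v)) else grepl("^O", colnames(v))
    filled <- imp$values[1, cols & is.na(v[1, ])]
    expect_gt(length(filled), 50)
    expect_lt(abs(mean(filled) - m_true), 4 * sd(filled) / sqrt(length(filled)))
  }
})

test_that("geNorm M matches a brute-force pairwise-SD double loop", {
  set.seed(6)
  for (rep in 1:3) {
    m <- named_matrix(rnorm(10 * 20, 30, 2), 10)
    got <- genorm_m(m)
    brute <- sapply(1:10, function(i) {
      mean(sapply(setdiff(1:10, i), function(j) sd(m[i, ] - m[j, ])))
    })
    expect_lt(max(abs(got$genorm_m - brute)), 1e-12)
  }
})

test_that("comparative delta-Ct equals the first geNorm iteration exactly", {
  set.seed(7)
  m <- named_matrix(rnorm(8 * 15, 28, 1.5), 8)
  expect_identical(comparative_deltact(m)$deltact_score, genorm_m(m)$genorm_m)

  # two genes: both scores are the SD of their difference
  m2 <- m[1:2, ]
  cd <- comparative_deltact(m2)
  expect_equal(cd$deltact_score, rep(sd(m2[1, ] - m2[2, ]), 2))
})

test_that("a perfectly co-stable pair survives geNorm elimination to the end", {
  set.seed(8)
  m <- named_matrix(rnorm(5 * 12, 30, 1), 5)
  m[2, ] <- m[1, ] + 3  # constant shift: SD(t1 - t2) = 0
  g <- genorm_m(m)
  expect_equal(g$genorm_rank[1:2], c(1.5, 1.5))

  # adding a per-sample constant to all genes changes no M value
  shift <- rnorm(12)
  g2 <- genorm_m(sweep(m, 2, shift, "+"))
  expect_equal(g2$genorm_m, g$genorm_m, tolerance = 1e-12)
})

test_that("BestKeeper statistics match direct arithmetic", {
  set.seed(9)
  m <- named_matrix(rnorm(3 * 5, 25, 2), 3)
  bk <- bestkeeper_stats(m)
  expect_equal(bk$bestkeeper_sd, unname(apply(m, 1, sd)))
  expect_equal(bk$bestkeeper_cv, unname(100 * apply(m, 1, sd) / rowMeans(m)))
  expect_equal(bk$bestkeeper_r,
               unname(apply(m, 1, function(x) cor(x, colMeans(m)))))
  expect_equal(bk$bestkeeper_rank, unname(rank(apply(m, 1, sd))))

  # constant gene: sd = cv = 0, rank 1, r set to 1 by convention
  m[1, ] <- 30
  expect_message(bk2 <- bestkeeper_stats(m), "zero-variance")
  expect_equal(bk2$bestkeeper_sd[1], 0)
  expect_equal(bk2$bestkeeper_cv[1], 0)
  expect_equal(bk2$bestkeeper_r[1], 1)
  expect_equal(bk2$bestkeeper_rank[1], 1)

  # two perfectly correlated genes both correlate perfectly with a 2-gene index
  m3 <- named_matrix(c(rnorm(6, 30, 1)), 1)
  m3 <- rbind(t1 = m3[1, ], t2 = 2 * m3[1, ] - 25)
  colnames(m3) <- paste0("C", 1:6)
  bk3 <- bestkeeper_stats(m3)
  expect_equal(bk3$bestkeeper_r, c(1, 1))
})

test_that("NormFinder favors the planted no-effect low-variance gene", {
  set.seed(10)
  wins <- 0
  for (rep in 1:100) {
    k <- 8; n <- 12
    eff <- rnorm(k - 1, 0, 1)
    eff <- c(0, eff - mean(eff))  # interactions sum to zero, as in the model
    sig <- c(0.1, runif(k - 1, 0.5, 1.5))
    samp <- rnorm(2 * n, 0, 1)
    m <- matrix(0, k, 2 * n)
    for (i in 1:k)
      m[i, ] <- 30 + samp + eff[i] * rep(c(0, 1), each = n) +
        rnorm(2 * n, 0, sig[i])
    dimnames(m) <- list(paste0("t", 1:k), paste0("S", 1:(2 * n)))
    nf <- normfinder_stability(m, rep(c("CNT", "END"), each = n))
    if (which.min(nf$normfinder_stability) == 1) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("NormFinder is location-invariant and matches a loop-based oracle", {
  set.seed(11)
  k <- 5; n <- 12
  m <- named_matrix(rnorm(k * 2 * n, 30, 1), k, sprefix = "S")
  grp <- rep(c("CNT", "END"), each = n)
  nf <- normfinder_stability(m, grp)

  # adding a constant to one gene everywhere changes nothing
  m2 <- m; m2[3, ] <- m2[3, ] + 7
  nf2 <- normfinder_stability(m2, grp)
  expect_equal(nf2$normfinder_stability, nf$normfinder_stability,
               tolerance = 1e-12)

  # brute-force decomposition with explicit loops on the same fixture
  glev <- c("CNT", "END")
  sig2 <- gmean <- matrix(0, k, 2)
  for (gi in 1:2) {
    sub <- m[, grp == glev[gi]]
    res <- matrix(0, k, n)
    for (i in 1:k) for (j in 1:n)
      res[i, j] <- sub[i, j] - mean(sub[i, ]) - mean(sub[, j]) + mean(sub)
    t_ig <- sapply(1:k, function(i) sum(res[i, ]^2) / (n - 1))
    sbar2 <- mean(t_ig) * k / (k - 1)
    sig2[, gi] <- pmax((t_ig - sbar2 / k) / (1 - 2 / k), 1e-12)
    gmean[, gi] <- rowMeans(sub)
  }
  d <- matrix(0, k, 2)
  for (i in 1:k) for (gi in 1:2)
    d[i, gi] <- gmean[i, gi] - mean(gmean[i, ]) - mean(gmean[, gi]) +
      mean(gmean)
  var_d <- sig2 / n
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (2 - 1)) - mean(var_d))
  d_sh <- d * gamma2 / (gamma2 + var_d)
  oracle <- rowMeans(abs(d_sh)) + rowMeans(sqrt(var_d))
  expect_equal(nf$normfinder_stability, unname(oracle), tolerance = 1e-12)
})

test_that("NormFinder ranking of a no-effect gene is robust to label permutation", {
  set.seed(12)
  k <- 6; n <- 10
  sig <- c(0.1, runif(k - 1, 0.8, 1.5))
  m <- named_matrix(30 + rnorm(k * 2 * n, 0, 1) * sig, k, sprefix = "S")
  ranks <- replicate(50, {
    grp <- sample(rep(c("A", "B"), each = n))
    nf <- normfinder_stability(m, grp)
    nf$normfinder_rank[1]
  })
  expect_lte(median(ranks), 2)
})

test_that("rank aggregation is the geometric mean, symmetric in algorithms", {
  expect_equal(aggregate_ranks(matrix(c(1, 2, 2, 4), 1)), 2)
  expect_equal(aggregate_ranks(matrix(rep(1, 4), 1)), 1)
  r <- matrix(c(1, 2, 3, 2, 1, 3, 3, 2, 1, 1, 3, 2), 3)
  expect_equal(aggregate_ranks(r), aggregate_ranks(r[, c(3, 1, 4, 2)]))
  expect_error(aggregate_ranks(matrix(c(1, NA), 1)), "missing")
})

test_that("stability algorithms are equivariant under target relabeling", {
  set.seed(13)
  m <- named_matrix(rnorm(6 * 16, 30, 1.5), 6, sprefix = "S")
  grp <- rep(c("CNT", "END"), each = 8)
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- m[perm, ]
  expect_equal(genorm_m(mp)$genorm_m, genorm_m(m)$genorm_m[perm])
  expect_equal(comparative_deltact(mp)$deltact_score,
               comparative_deltact(m)$deltact_score[perm])
  expect_equal(bestkeeper_stats(mp)$bestkeeper_sd,
               bestkeeper_stats(m)$bestkeeper_sd[perm])
  expect_equal(normfinder_stability(mp, grp)$normfinder_stability,
               normfinder_stability(m, grp)$normfinder_stability[perm])
})

test_that("selection returns the screened best candidates and their factor", {
  set.seed(14)
  n <- 20
  m <- rbind(t_const = rep(30, n),
             t_a = rnorm(n, 28, 1), t_b = rnorm(n, 32, 1.5),
             t_c = rnorm(n, 26, 2))
  colnames(m) <- c(paste0("C", 1:(n / 2)), paste0("O", 1:(n / 2)))
  grp <- rep(c("CNT", "END"), each = n / 2)
  stab <- stability_table(m, grp, tost_margin = 0.5,
                          detected_frac = setNames(rep(1, 4), rownames(m)))
  ct <- toy_ct(m)
  refset <- select_references(stab, ct, k = 1)
  expect_equal(refset$reference_ids, "t_const")
  expect_equal(unname(refset$norm_factor), rep(30, n))

  # too strict a screen is a clear error
  stab$detected_frac <- 0.5
  expect_error(select_references(stab, ct, k = 1), "pass the screens")
})
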