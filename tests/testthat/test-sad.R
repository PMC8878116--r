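test_that("broken-stick expectations are closed-form and conserve N", {
  expect_equal(fit_broken_stick(10)$expected_rank_abundance, 10)
  expect_equal(fit_broken_stick(c(3, 2, 1))$expected_rank_abundance,
               c(11 / 3, 5 / 3, 2 / 3))
  for (seed in 1:10) {
    set.seed(seed)
    v <- rpois(sample(2:50, 1), 10) + 1
    f <- fit_broken_stick(v)
    expect_equal(sum(f$expected_rank_abundance), sum(v), tolerance = 1e-12)
    expect_true(all(diff(f$expected_rank_abundance) <= 0))
  }
})

test_that("log-series alpha satisfies its defining equation", {
  # bisection oracle on S = alpha log(1 + N/alpha), N = 100, S = 20
  f <- function(a) a * log(1 + 100 / a) - 20
  lo <- 1e-9; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  v <- c(rep(1, 15), 2, 3, 5, 20, 55)  # S = 20, N = 100
  fit <- fit_logseries(v)
  expect_equal(unname(fit$params["alpha"]), lo, tolerance = 1e-6)
  # fixed-point identity to 1e-9, x in (0,1)
  a <- fit$params["alpha"]
  expect_lt(abs(a * log(1 + 100 / a) - 20), 1e-9)
  expect_gt(fit$params["x"], 0)
  expect_lt(fit$params["x"], 1)
  # cross-check against vegan's independent Fisher alpha
  expect_equal(unname(fit$params["alpha"]), vegan::fisher.alpha(v),
               tolerance = 1e-5)
  expect_error(fit_logseries(rep(1, 5)), "no solution")
})

test_that("Zipf exponent maximizes the multinomial rank likelihood", {
  v <- round(1200 * c(1, 1 / 2, 1 / 3, 1 / 4))
  expect_lt(abs(fit_zipf(v)$params["gamma"] - 1), 0.05)
  expect_lt(fit_zipf(rep(50, 6))$params["gamma"], 1e-3)
  # two ranks: closed form p1/p2 = 2^gamma
  expect_equal(unname(fit_zipf(c(900, 100))$params["gamma"]), log2(9),
               tolerance = 1e-4)
  # grid oracle: no gamma on a fine grid beats the optimizer
  v2 <- c(400, 180, 120, 80, 60, 40, 30, 20)
  ll <- function(g) {
    p <- seq_along(v2)^(-g); p <- p / sum(p)
    sum(sort(v2, decreasing = TRUE) * log(p))
  }
  fit <- fit_zipf(v2)
  grid_best <- max(vapply(seq(0, 5, by = 0.001), ll, numeric(1)))
  expect_gte(fit$log_likelihood + 1e-6, grid_best)
})

test_that("lognormal fit recovers log moments and flags degeneracy", {
  f <- fit_lognormal(c(2, 8, 32))
  lx <- log(c(2, 8, 32))
  expect_equal(unname(f$params["mu"]), mean(lx))
  expect_equal(unname(f$params["sigma"]), sqrt(mean((lx - mean(lx))^2)))
  expect_true(fit_lognormal(c(7, 7, 7))$degenerate)
  # scaling all abundances by c shifts mu by log(c), leaves sigma
  f4 <- fit_lognormal(4 * c(2, 8, 32))
  expect_equal(unname(f4$params["mu"]), mean(lx) + log(4))
  expect_equal(unname(f4$params["sigma"]), unname(f$params["sigma"]))
})

test_that("PLN pmf matches a peak-shifted quadrature oracle", {
  gh <- pracma::gaussHermite(61)
  for (par in list(c(0, 1), c(1, 2), c(2, 0.3))) {
    ns <- c(0, 1, 2, 5, 17, 100, 800)
    mine <- phyllocore:::pln_log_pmf(ns, par[1], par[2], gh)
    orc <- vapply(ns, oracle_pln_log_pmf, numeric(1),
                  mu = par[1], sigma = par[2])
    expect_lt(max(abs(mine - orc)), 1e-6)
  }
  # the pmf is a proper distribution
  expect_equal(sum(exp(phyllocore:::pln_log_pmf(0:20000, 1, 1.5, gh))), 1,
               tolerance = 1e-7)
})

test_that("PLN fit collapses sigma on pure Poisson data", {
  set.seed(4)
  v <- rpois(2000, exp(1))
  v <- v[v > 0]
  f <- fit_poisson_lognormal(v)
  expect_lte(unname(f$params["sigma"]), 0.1)
})

test_that("PLN estimate is a local likelihood optimum", {
  set.seed(5)
  v <- rpln_truncated(400, 1, 1)
  f <- fit_poisson_lognormal(v)
  gh <- pracma::gaussHermite(61)
  ll <- function(mu, sigma) {
    tab <- table(v)
    -phyllocore:::pln_negll(c(mu, log(sigma)),
                            as.numeric(names(tab)), as.numeric(tab), gh)
  }
  best <- ll(f$params["mu"], f$params["sigma"])
  expect_gte(best, ll(f$params["mu"] + 0.1, f$params["sigma"]))
  expect_gte(best, ll(f$params["mu"] - 0.1, f$params["sigma"]))
  expect_gte(best, ll(f$params["mu"], f$params["sigma"] + 0.1))
})

test_that("PLN fit is invariant to permutation of the abundance vector", {
  set.seed(6)
  v <- rpln_truncated(300, 0.5, 1.2)
  a <- fit_poisson_lognormal(v)
  b <- fit_poisson_lognormal(sample(v))
  expect_identical(a$params, b$params)
})

test_that("PLN and Zipf errors shrink as richness grows (consistency)", {
  set.seed(8)
  err <- sapply(c(100, 2000), function(s) {
    v <- rpln_truncated(s, 1, 1)
    f <- fit_poisson_lognormal(v)
    abs(f$params["sigma"] - 1) + abs(f$params["mu"] - 1)
  })
  expect_lt(err[2], err[1])
  gerr <- sapply(c(100, 2000), function(s) {
    p <- (1:s)^(-1.2); p <- p / sum(p)
    v <- as.numeric(rmultinom(1, 50 * s, p))
    abs(fit_zipf(v[v > 0])$params["gamma"] - 1.2)
  })
  expect_lt(gerr[2], gerr[1] + 0.02)
})

test_that("variation explained is an R^2 on log10 rank abundance", {
  expect_equal(variation_explained(c(100, 10, 1), c(100, 10, 1)), 100)
  # constant expectation at the log-mean defines 0%
  obs <- c(100, 10, 1)
  expect_equal(variation_explained(obs, rep(10^mean(log10(obs)), 3)), 0)
  # hand-computed sums of squares
  lo <- log10(c(100, 10, 1)); le <- log10(c(50, 20, 2))
  hand <- 100 * (1 - sum((lo - le)^2) / sum((lo - mean(lo))^2))
  expect_equal(variation_explained(c(100, 10, 1), c(50, 20, 2)), hand)
  expect_error(variation_explained(1:3, 1:4), "lengths differ")
})

test_that("model comparison behaves at the even and uneven limits", {
  # perfectly even community: Zipf (gamma ~ 0) reproduces it exactly
  even <- otu_table(matrix(100, 2, 12,
                           dimnames = list(c("s1", "s2"), NULL)))
  cmp <- compare_sad_models(even, models = c("zipf", "broken_stick"))
  s <- cmp$summary
  expect_equal(s$mean_variation_explained[s$model == "zipf"], 100,
               tolerance = 1e-6)
  # under the log10 R^2 score a nonzero-residual model is -Inf here
  expect_true(s$mean_variation_explained[s$model == "broken_stick"] < 0)
  # strongly uneven lognormal community: broken stick ranks last
  set.seed(9)
  v <- rpln_truncated(500, 0.5, 2)
  tabu <- otu_table(matrix(v, 1, 500, dimnames = list("s1", NULL)),
                    require_positive_samples = TRUE)
  cmpu <- compare_sad_models(tabu)
  expect_equal(cmpu$summary$model[nrow(cmpu$summary)], "broken_stick")
})

test_that("pooled comparison fits the concatenated community once", {
  tab <- random_table(4, 80, seed = 33)
  cmp <- compare_sad_models(tab, pooled = TRUE,
                            models = c("zipf", "broken_stick"))
  expect_length(cmp$fits, 1)
  expect_equal(names(cmp$fits), "pooled")
})
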