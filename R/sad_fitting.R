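#' Abundance vector of one community
#'
#' The species abundance distribution (SAD) describes, for one community,
#' how many individuals (reads) each observed species (OTU) has. Zeros are
#' excluded: species never observed sit behind the sampling "veil" and are
#' handled by zero-truncation in the Poisson-lognormal model.
#'
#' @param x non-negative numeric vector (a sample's OTU counts).
#' @return sorted (decreasing) positive integer vector with attributes
#'   `N` (total reads) and `S` (observed species).
#' @export
as_abundance_vector <- function(x) {
  if (any(x < 0) || any(!is.finite(x))) stop("abundances must be finite, >= 0")
  v <- sort(x[x > 0], decreasing = TRUE)
  if (!length(v)) stop("no positive abundances")
  if (any(abs(v - round(v)) > 1e-8)) stop("abundances must be integer counts")
  v <- round(v)
  structure(v, N = sum(v), S = length(v))
}

sad_result <- function(model, params, log_likelihood, observed, expected,
                       ...) {
  ve <- variation_explained(observed, expected)
  structure(list(model = model, params = params,
                 log_likelihood = log_likelihood,
                 variation_explained = ve,
                 expected_rank_abundance = expected,
                 observed = as.numeric(observed), ...),
            class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("sad_fit[%s]: S = %d, variation explained = %.2f%%\n",
              x$model, length(x$observed), x$variation_explained))
  if (length(x$params))
    cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Broken-stick (random niche apportionment) SAD
#'
#' Parameter-free null model: the expected abundance of the i-th ranked
#' species among S species sharing N reads is (N/S) * sum_{k=i..S} 1/k.
#' Expectations conserve N exactly.
#'
#' @param v abundance vector (coerced via [as_abundance_vector()]).
#' @return a `sad_fit` (no free parameters, `log_likelihood` NA).
#' @export
fit_broken_stick <- function(v) {
  v <- as_abundance_vector(v)
  s <- attr(v, "S"); n <- attr(v, "N")
  expected <- (n / s) * rev(cumsum(rev(1 / seq_len(s))))
  sad_result("broken_stick", numeric(0), NA_real_, v, expected)
}

#' Fisher log-series SAD
#'
#' Fits alpha from S = alpha * ln(1 + N / alpha) by bracketed root-finding
#' (|S_pred - S| <= 1e-9), with x = N / (N + alpha). The species-level
#' abundance law is phi(n) = alpha x^n / n; expected rank abundances are its
#' quantiles at (i - 0.5) / S.
#'
#' @inheritParams fit_broken_stick
#' @return a `sad_fit` with params `alpha`, `x`.
#' @export
fit_logseries <- function(v) {
  v <- as_abundance_vector(v)
  s <- attr(v, "S"); n <- attr(v, "N")
  if (s < 2) stop("log-series fit needs S >= 2")
  if (n <= s)
    stop("log-series has no solution when N <= S (all singletons)")
  f <- function(a) a * log1p(n / a) - s
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  alpha <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  # polish by Newton so the defining identity holds to 1e-9
  for (i in 1:50) {
    if (abs(f(alpha)) <= 1e-10) break
    fp <- log1p(n / alpha) - n / (alpha + n)
    alpha <- alpha - f(alpha) / fp
  }
  x <- n / (n + alpha)
  # species-level pmf q(k) = alpha x^k / (k S); quantiles by cumulative sum
  probs <- (seq_len(s) - 0.5) / s
  q <- logseries_quantiles(alpha, x, s, n, probs)
  ll <- sum(log(alpha) + v * log(x) - log(as.numeric(v)) - log(s))
  sad_result("logseries", c(alpha = alpha, x = x), ll, v,
             sort(q, decreasing = TRUE))
}

logseries_quantiles <- function(alpha, x, s, n, probs) {
  nmax <- max(n, 10)
  k <- seq_len(nmax)
  cdf <- cumsum(alpha * exp(k * log(x) - log(k)) / s)
  cdf <- cdf / max(cdf[nmax], 1)  # guard tiny truncation remainder
  vapply(probs, function(p) k[which(cdf >= p)[1]], numeric(1))
}

#' Zipf rank-abundance SAD
#'
#' Rank model p_i proportional to i^(-gamma); gamma is the maximizer of the
#' multinomial likelihood of the observed counts over ranks (gamma >= 0).
#' Expected rank abundances are N * p_i.
#'
#' @inheritParams fit_broken_stick
#' @return a `sad_fit` with param `gamma`.
#' @export
fit_zipf <- function(v) {
  v <- as_abundance_vector(v)
  s <- attr(v, "S"); n <- attr(v, "N")
  if (s < 2) stop("Zipf fit needs S >= 2")
  ranks <- seq_len(s)
  negll <- function(g) {
    lp <- -g * log(ranks)
    lp <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
    -sum(v * lp)
  }
  opt <- stats::optimize(negll, c(0, 30))
  gamma <- if (negll(0) <= opt$objective) 0 else opt$minimum
  p <- ranks^(-gamma); p <- p / sum(p)
  sad_result("zipf", c(gamma = gamma), -negll(gamma), v, n * p)
}

#' Continuous lognormal SAD
#'
#' Maximum-likelihood fit of a lognormal to the observed abundances: mu and
#' sigma are the mean and (population) sd of log abundance. sigma = 0 is
#' flagged degenerate. Expected rank abundances are lognormal quantiles at
#' (i - 0.5) / S.
#'
#' @inheritParams fit_broken_stick
#' @return a `sad_fit` with params `mu`, `sigma` and a `degenerate` flag.
#' @export
fit_lognormal <- function(v) {
  v <- as_abundance_vector(v)
  s <- attr(v, "S")
  if (s < 2) stop("lognormal fit needs S >= 2")
  lx <- log(as.numeric(v))
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  probs <- (seq_len(s) - 0.5) / s
  expected <- sort(exp(mu + sigma * stats::qnorm(probs)), decreasing = TRUE)
  ll <- if (sigma > 0) sum(stats::dlnorm(v, mu, sigma, log = TRUE)) else Inf
  sad_result("lognormal", c(mu = mu, sigma = sigma), ll, v, expected,
             degenerate = sigma == 0)
}

# ---- zero-truncated Poisson-lognormal -------------------------------------

# log P(n) for PLN(mu, sigma) at each n, by mode-centered Gauss-Hermite
# quadrature. In u = log(lambda),
#   P(n) = 1/(n! sigma sqrt(2 pi)) * int exp(h(u)) du,
#   h(u) = n u - e^u - (u - mu)^2 / (2 sigma^2).
# The Poisson kernel narrows like 1/sqrt(n), so quadrature anchored on the
# lognormal alone undersamples it badly for large counts; instead the nodes
# are recentered and rescaled per count at the integrand's Laplace mode
# (Newton iteration on the concave h).
pln_log_pmf <- function(n, mu, sigma, gh) {
  n <- as.numeric(n)
  s2 <- sigma^2
  u <- ifelse(n > 0, log(pmax(n, 1)), mu - s2)
  for (i in 1:50) {
    eu <- exp(u)
    h1 <- n - eu - (u - mu) / s2
    h2 <- -eu - 1 / s2
    step <- h1 / h2
    u <- u - step
    if (max(abs(step)) < 1e-12) break
  }
  scl <- 1 / sqrt(exp(u) + 1 / s2)          # local Gaussian sd of exp(h)
  uu <- outer(u, rep(1, length(gh$x))) +
    sqrt(2) * outer(scl, gh$x)
  h <- n * uu - exp(uu) - (uu - mu)^2 / (2 * s2)
  lw <- log(gh$w) + gh$x^2                  # modified GH weights, O(1)
  m <- apply(h, 1, max)
  -lgamma(n + 1) - log(sigma) - 0.5 * log(2 * pi) +
    0.5 * log(2) + log(scl) + m +
    log(rowSums(exp(sweep(h, 1, m, "-") + outer(rep(1, length(n)), lw))))
}

pln_negll <- function(par, counts, mult, gh) {
  mu <- par[1]; sigma <- exp(par[2])
  lp <- pln_log_pmf(c(0, counts), mu, sigma, gh)
  p0 <- exp(lp[1])
  if (p0 >= 1 - 1e-12) return(1e10)
  -sum(mult * (lp[-1] - log1p(-p0)))
}

#' Zero-truncated Poisson-lognormal SAD (maximum likelihood)
#'
#' The Poisson-lognormal arises when each species' true mean abundance is
#' lognormal and reads are Poisson draws around it; zero truncation removes
#' the unobserved species below the sampling veil. The marginal probability
#' P(n) = integral Poisson(n; lambda) Lognormal(lambda; mu, sigma) dlambda
#' is evaluated by Gauss-Hermite quadrature (61 nodes by default) and the
#' truncated likelihood is maximized by bounded quasi-Newton (L-BFGS-B)
#' from four deterministic moment-based starts; ties are broken by highest
#' likelihood then smallest sigma. Expected rank abundances are quantiles
#' of the fitted zero-truncated count distribution at (i - 0.5) / S.
#'
#' @inheritParams fit_broken_stick
#' @param n_nodes Gauss-Hermite nodes (>= 60 recommended).
#' @return a `sad_fit` with params `mu`, `sigma` and a `converged` flag.
#' @export
fit_poisson_lognormal <- function(v, n_nodes = 61) {
  v <- as_abundance_vector(v)
  s <- attr(v, "S")
  if (s < 2) stop("Poisson-lognormal fit needs S >= 2")
  gh <- pracma::gaussHermite(n_nodes)
  tab <- table(as.numeric(v))
  counts <- as.numeric(names(tab))
  mult <- as.numeric(tab)
  lx <- log(as.numeric(v))
  m <- mean(lx); sd0 <- max(stats::sd(lx), 0.1)
  starts <- list(c(m, log(sd0)),
                 c(m - sd0^2 / 2, log(sd0)),
                 c(m, log(sd0 / 2)),
                 c(0, 0))
  fits <- lapply(starts, function(p0)
    tryCatch(stats::optim(p0, pln_negll, counts = counts, mult = mult,
                          gh = gh, method = "L-BFGS-B",
                          lower = c(-20, log(1e-3)),
                          upper = c(20, log(10))),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("Poisson-lognormal fit failed to converge from all starts")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  sig <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- fits[[order(vals, sig)[1]]]
  mu <- best$par[1]; sigma <- exp(best$par[2])
  probs <- (seq_len(s) - 0.5) / s
  expected <- pln_truncated_quantiles(mu, sigma, gh, probs,
                                      nmax = max(10 * max(v), 1000))
  sad_result("poisson_lognormal", c(mu = mu, sigma = sigma),
             -best$value, v, sort(expected, decreasing = TRUE),
             converged = best$convergence == 0)
}

# quantiles of the zero-truncated PLN count law, chunked cumulative pmf
pln_truncated_quantiles <- function(mu, sigma, gh, probs, nmax) {
  p0 <- exp(pln_log_pmf(0, mu, sigma, gh))
  out <- rep(NA_real_, length(probs))
  cdf_done <- 0
  lo <- 1
  chunk <- 2048
  while (anyNA(out) && lo <= nmax) {
    hi <- min(lo + chunk - 1, nmax)
    pm <- exp(pln_log_pmf(lo:hi, mu, sigma, gh)) / (1 - p0)
    cdf <- cdf_done + cumsum(pm)
    for (j in which(is.na(out))) {
      hit <- which(cdf >= probs[j])
      if (length(hit)) out[j] <- (lo:hi)[hit[1]]
    }
    cdf_done <- cdf[length(cdf)]
    lo <- hi + 1
    chunk <- chunk * 2
  }
  out[is.na(out)] <- nmax  # numerically unreachable upper tail
  out
}

#' Percent variation explained on log10 rank abundance
#'
#' The model-comparison score: R^2 = 100 * (1 - SS_res / SS_tot) computed
#' on log10 abundance of the rank-ordered observed vector against the
#' model's expected rank abundances. 100 means a perfect fit; values can be
#' negative for models worse than the flat mean.
#'
#' @param observed positive abundances (rank order is enforced internally).
#' @param expected positive expected rank abundances, same length.
#' @return percentage (<= 100).
#' @export
variation_explained <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ")
  lo <- log10(sort(as.numeric(observed), decreasing = TRUE))
  le <- log10(sort(as.numeric(expected), decreasing = TRUE))
  ss_res <- sum((lo - le)^2)
  ss_tot <- sum((lo - mean(lo))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 100 else -Inf)
  100 * (1 - ss_res / ss_tot)
}

#' Fit and compare the five SAD models
#'
#' Fits broken-stick, log-series, Zipf, lognormal and zero-truncated
#' Poisson-lognormal to each sample's abundance vector (or to the pooled
#' community with `pooled = TRUE`) and ranks the models by mean variation
#' explained. Per-sample fit failures are recorded and that sample is
#' excluded from the failing model's mean, with a warning.
#'
#' @param table an [otu_table].
#' @param pooled fit the column-summed community instead of per-sample.
#' @param models subset of the five model names.
#' @return list of class `sad_comparison`: `summary` data.frame (model,
#'   mean/sd variation explained, n_fits, n_failures), `best_model`, and
#'   `fits` (per sample per model).
#' @export
compare_sad_models <- function(table, pooled = FALSE,
                               models = c("poisson_lognormal", "lognormal",
                                          "logseries", "zipf",
                                          "broken_stick")) {
  stopifnot_otu_table(table)
  fitters <- list(poisson_lognormal = fit_poisson_lognormal,
                  lognormal = fit_lognormal,
                  logseries = fit_logseries,
                  zipf = fit_zipf,
                  broken_stick = fit_broken_stick)
  models <- match.arg(models, names(fitters), several.ok = TRUE)
  vectors <- if (pooled) list(pooled = colSums(table$counts)) else
    stats::setNames(lapply(seq_len(n_samples(table)), function(i)
      table$counts[i, ]), sample_ids(table))
  fits <- lapply(vectors, function(x) {
    lapply(fitters[models], function(f)
      tryCatch(f(x), error = function(e) structure(
        list(error = conditionMessage(e)), class = "sad_fit_failure")))
  })
  summary <- do.call(rbind, lapply(models, function(mname) {
    ve <- vapply(fits, function(fs) {
      f <- fs[[mname]]
      if (inherits(f, "sad_fit_failure")) NA_real_ else
        f$variation_explained
    }, numeric(1))
    data.frame(model = mname,
               mean_variation_explained = mean(ve, na.rm = TRUE),
               sd_variation_explained =
                 if (sum(!is.na(ve)) > 1) stats::sd(ve, na.rm = TRUE)
               else NA_real_,
               n_fits = sum(!is.na(ve)), n_failures = sum(is.na(ve)),
               stringsAsFactors = FALSE)
  }))
  if (any(summary$n_failures > 0))
    warning("SAD fit failures: ",
            paste(sprintf("%s (%d)", summary$model, summary$n_failures)[
              summary$n_failures > 0], collapse = ", "))
  summary <- summary[order(-summary$mean_variation_explained), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, best_model = summary$model[1],
                 fits = fits, pooled = pooled),
            class = "sad_comparison")
}

#' @export
print.sad_comparison <- function(x, ...) {
  cat(sprintf("SAD model comparison (%s):\n",
              if (x$pooled) "pooled" else
                sprintf("%d samples", length(x$fits))))
  print(x$summary, digits = 4)
  cat("best model:", x$best_model, "\n")
  invisible(x)
}
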