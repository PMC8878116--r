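# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package) so
# they can stand as second opinions.

# the worked 4-sample x 5-OTU table: core should be {A, C}
worked_core_table <- function() {
  m <- rbind(c(50, 30, 15, 4, 1),
             c(40, 35, 20, 4, 1),
             c(45, 0, 50, 4, 1),
             c(55, 25, 15, 4, 1))
  dimnames(m) <- list(paste0("s", 1:4), c("A", "B", "C", "D", "E"))
  otu_table(m)
}

random_table <- function(n_samples, n_otus, max_count = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_otus, runif(1, 0.5, 4)) *
                  rbinom(n_samples * n_otus, 1, runif(1, 0.3, 0.9)),
                n_samples, n_otus)
    m <- pmin(m, max_count)
    if (all(rowSums(m) > 0)) break
  }
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("o%03d", seq_len(n_otus)))
  otu_table(m)
}

# --- brute-force core selection ------------------------------------------
brute_force_core <- function(tab, mean_ra_min = 0.01, occupancy_min = 0.8,
                             abundant_cumulative = 0.8,
                             abundant_frac_min = 0.5) {
  m <- tab$counts
  ns <- nrow(m); no <- ncol(m)
  core <- character(0)
  for (j in seq_len(no)) {
    ras <- numeric(ns); occ <- 0; ab <- 0
    for (i in seq_len(ns)) {
      ras[i] <- m[i, j] / sum(m[i, ])
      if (m[i, j] >= 1) occ <- occ + 1
      # abundant set of sample i by explicit walk
      ord <- order(-m[i, ], colnames(m), method = "radix")
      cum <- 0; inset <- FALSE
      for (k in ord) {
        cum <- cum + m[i, k] / sum(m[i, ])
        if (k == j) { inset <- TRUE; break }
        if (cum >= abundant_cumulative - 1e-12) break
      }
      if (inset) ab <- ab + 1
    }
    if (mean(ras) > mean_ra_min && occ / ns > occupancy_min &&
        ab / ns >= abundant_frac_min)
      core <- c(core, colnames(m)[j])
  }
  core
}

# --- exhaustive UniFrac branch walk --------------------------------------
# lists every branch of the tree with its length and descendant tip set by
# naive recursion over the edge table
tree_branches <- function(tree) {
  nt <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  lapply(seq_len(nrow(tree$edge)), function(e)
    list(length = tree$edge.length[e],
         tips = tips_below(tree$edge[e, 2])))
}

oracle_unweighted_unifrac <- function(tree, s1, s2) {
  num <- 0; den <- 0
  for (b in tree_branches(tree)) {
    in1 <- any(b$tips %in% s1); in2 <- any(b$tips %in% s2)
    if (in1 || in2) den <- den + b$length
    if (xor(in1, in2)) num <- num + b$length
  }
  if (den == 0) 0 else num / den
}

oracle_weighted_unifrac <- function(tree, a1, a2, normalized = TRUE) {
  a1 <- a1 / sum(a1); a2 <- a2 / sum(a2)
  num <- 0; den <- 0
  for (b in tree_branches(tree)) {
    p1 <- sum(a1[names(a1) %in% b$tips])
    p2 <- sum(a2[names(a2) %in% b$tips])
    num <- num + b$length * abs(p1 - p2)
    den <- den + b$length * (p1 + p2)
  }
  if (!normalized) num else if (den == 0) 0 else num / den
}

# --- PLN pmf oracle: quadrature shifted to the integrand's peak ----------
oracle_pln_log_pmf <- function(n, mu, sigma) {
  h <- function(u) n * u - exp(u) - (u - mu)^2 / (2 * sigma^2)
  um <- optimize(h, c(mu - 15 * sigma,
                      max(mu + 15 * sigma, log(n + 1) + 5)),
                 maximum = TRUE)$maximum
  hm <- h(um)
  val <- integrate(function(u) exp(h(u) - hm), um - 30, um + 30,
                   rel.tol = 1e-12)$value
  hm + log(val) - lgamma(n + 1) - log(sigma * sqrt(2 * pi))
}

# zero-truncated PLN sampler (for parameter-recovery tests)
rpln_truncated <- function(s, mu, sigma) {
  out <- integer(0)
  while (length(out) < s) {
    lam <- rlnorm(2 * s, mu, sigma)
    n <- rpois(2 * s, lam)
    out <- c(out, n[n > 0])
  }
  out[seq_len(s)]
}
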