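#' Alpha-diversity indices
#'
#' Shannon and Simpson measure community diversity; Chao1 and ACE estimate
#' richness from the frequencies of rare OTUs. All operate on one sample's
#' non-negative count vector and error on an all-zero vector.
#'
#' * `shannon_index`: H = -sum p_i log_base p_i over non-zero p_i. The base
#'   defaults to 2 (the convention of the QIIME 1.x lineage of tools).
#' * `simpson_index`: 1 - sum p_i^2, in `[0, 1)`.
#' * `chao1_index`: classic estimator S_obs + F1^2 / (2 F2) with the
#'   bias-corrected form S_obs + F1 (F1 - 1) / 2 when no doubletons exist
#'   (F1, F2 = numbers of singleton and doubleton OTUs).
#' * `ace_index`: abundance-based coverage estimator with the rare/abundant
#'   split at `rare_threshold` reads; undefined (error) when all rare reads
#'   are singletons, since sample coverage is then zero — use Chao1 there.
#'
#' @param counts non-negative numeric vector of per-OTU read counts.
#' @param base logarithm base for Shannon (> 1).
#' @param rare_threshold counts <= this are "rare" for ACE (default 10).
#' @return a single numeric value.
#' @examples
#' shannon_index(c(10, 10, 10, 10))   # 2 bits
#' chao1_index(c(1, 1, 2, 3))         # 6
#' @export
shannon_index <- function(counts, base = 2) {
  p <- positive_props(counts)
  if (base <= 1) stop("log base must be > 1")
  -sum(p * log(p, base = base))
}

#' @rdname shannon_index
#' @export
simpson_index <- function(counts) {
  p <- positive_props(counts)
  1 - sum(p^2)
}

#' @rdname shannon_index
#' @export
chao1_index <- function(counts) {
  n <- check_counts(counts)
  s_obs <- sum(n > 0)
  f1 <- sum(n == 1)
  f2 <- sum(n == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' @rdname shannon_index
#' @export
ace_index <- function(counts, rare_threshold = 10) {
  n <- check_counts(counts)
  n <- n[n > 0]
  rare <- n[n <= rare_threshold]
  s_abund <- sum(n > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0)
    stop("ACE is undefined: all rare reads are singletons (coverage 0); ",
         "consider Chao1")
  fk <- vapply(seq_len(rare_threshold), function(k) sum(rare == k),
               numeric(1))
  gamma2 <- max(
    s_rare / c_ace * sum(seq_len(rare_threshold) *
                           (seq_len(rare_threshold) - 1) * fk) /
      (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

check_counts <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

positive_props <- function(counts) {
  n <- check_counts(counts)
  n <- n[n > 0]
  n / sum(n)
}

#' Per-sample diversity profile
#'
#' Computes observed OTUs, Shannon, Simpson, Chao1 and ACE for every sample
#' of a table. ACE is `NA` (with a warning naming the samples) where its
#' coverage is zero.
#'
#' @param table an [otu_table].
#' @param base Shannon log base.
#' @param rare_threshold ACE rare/abundant split.
#' @return data.frame with one row per sample.
#' @export
diversity_profile <- function(table, base = 2, rare_threshold = 10) {
  stopifnot_otu_table(table)
  m <- table$counts
  ace <- vapply(seq_len(nrow(m)), function(i)
    tryCatch(ace_index(m[i, ], rare_threshold), error = function(e)
      NA_real_), numeric(1))
  if (anyNA(ace))
    warning("ACE undefined (zero coverage) for sample(s): ",
            paste(rownames(m)[is.na(ace)], collapse = ", "))
  data.frame(
    sample_id = rownames(m),
    observed_otus = rowSums(m > 0),
    shannon = apply(m, 1, shannon_index, base = base),
    simpson = apply(m, 1, simpson_index),
    chao1 = apply(m, 1, chao1_index),
    ace = ace,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefaction curve
#'
#' Randomly subsamples each sample without replacement to each requested
#' depth, `n_iterations` times, and reports the mean and sd of a diversity
#' index per sample per depth. Depths exceeding a sample's total are
#' reported as `NA` for that sample. At a sample's full depth the index
#' equals the plug-in (unrarefied) value exactly.
#'
#' @param table an [otu_table].
#' @param depths increasing positive integer read depths; default 10 evenly
#'   spaced depths up to the smallest sample total.
#' @param index function of a count vector, e.g. [shannon_index()].
#' @param n_iterations random subsamples per depth (default 10).
#' @param seed integer seed making the whole curve reproducible.
#' @return data.frame with columns sample_id, depth, mean, sd, n_iterations.
#' @export
rarefaction_curve <- function(table, depths = NULL, index = shannon_index,
                              n_iterations = 10, seed = 1L) {
  stopifnot_otu_table(table)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  totals <- rowSums(table$counts)
  if (is.null(depths))
    depths <- unique(round(seq(1, min(totals), length.out = 10)))
  if (any(depths < 1)) stop("depths must be positive")
  depths <- sort(unique(as.integer(depths)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- expand.grid(sample_id = sample_ids(table), depth = depths,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    x <- table$counts[out$sample_id[r], ]
    d <- out$depth[r]
    if (d > sum(x)) next  # undefined point
    vals <- vapply(seq_len(n_iterations), function(i)
      index(subsample_counts(x, d)), numeric(1))
    out$mean[r] <- mean(vals)
    out$sd[r] <- stats::sd(vals)
  }
  out$n_iterations <- n_iterations
  out
}

# multivariate-hypergeometric subsample (without replacement); at full
# depth this is the identity, making the rarefaction exactness property hold
subsample_counts <- function(x, depth) {
  tot <- sum(x)
  if (depth == tot) return(x)
  # rrarefy warns whenever the smallest positive count exceeds 1, which is
  # routine for subsampled count vectors; the draw itself is exact
  suppressWarnings(drop(vegan::rrarefy(matrix(x, nrow = 1), depth)))
}

#' Species accumulation curve
#'
#' Mean and sd of the cumulative number of distinct OTUs over random
#' orderings of the samples; judges whether sampling was sufficient. When
#' the number of distinct orderings `n_samples!` does not exceed
#' `n_permutations`, all orderings are enumerated and the mean is exact;
#' otherwise `n_permutations` random orderings are drawn.
#'
#' @param table an [otu_table].
#' @param n_permutations orderings to average over (default 100).
#' @param seed integer seed.
#' @return data.frame with columns k, mean, sd, n_orderings, exact.
#' @export
accumulation_curve <- function(table, n_permutations = 100, seed = 1L) {
  stopifnot_otu_table(table)
  pres <- table$counts > 0
  n <- nrow(pres)
  exact <- factorial(n) <= n_permutations
  orders <- if (exact) {
    perms <- rbind(seq_len(n), as.matrix(permute::allPerms(n)))
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    lapply(seq_len(n_permutations), function(i) sample.int(n))
  }
  rich <- vapply(orders, function(o) {
    seen <- rep(FALSE, ncol(pres))
    vapply(o, function(s) {
      seen <<- seen | pres[s, ]
      sum(seen)
    }, numeric(1))
  }, numeric(n))
  rich <- matrix(rich, nrow = n)
  data.frame(k = seq_len(n),
             mean = rowMeans(rich),
             sd = apply(rich, 1, stats::sd),
             n_orderings = length(orders), exact = exact)
}
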