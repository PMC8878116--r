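#' Kruskal-Wallis screen for differential taxa
#'
#' Stage 1 of the LEfSe-style workflow: a rank-based Kruskal-Wallis test
#' (with tie correction, via [stats::kruskal.test()]) of each taxon's
#' relative abundance across groups. Taxa constant across all samples have
#' an undefined statistic and are excluded with a note.
#'
#' @param table an [otu_table].
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param alpha screening level (default 0.05).
#' @return data.frame: taxon, p_value, pass; attribute `excluded` lists
#'   constant taxa.
#' @export
kruskal_wallis_screen <- function(table, groups, alpha = 0.05) {
  stopifnot_otu_table(table)
  groups <- as.character(groups)
  if (length(groups) != n_samples(table))
    stop("groups length must match the table")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 groups with >= 2 samples each")
  ra <- relative_abundance(table)
  g <- factor(groups)
  p <- vapply(seq_len(ncol(ra)), function(j) {
    x <- ra[, j]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::kruskal.test(x, g)$p.value
  }, numeric(1))
  out <- data.frame(taxon = otu_ids(table), p_value = p,
                    pass = !is.na(p) & p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  excluded <- out$taxon[is.na(p)]
  if (length(excluded))
    attr(out, "excluded") <- excluded
  out
}

# stratified subsample indices: ceil(frac * n_g) per group, each group
# keeps at least one sample
lefse_subsample <- function(g, frac) {
  unlist(lapply(levels(g), function(lv) {
    idx <- which(g == lv)
    sample(idx, max(1, ceiling(frac * length(idx))))
  }))
}

# Fisher LDA effect sizes for one two-class contrast on scaled abundances
lda_contrast_effect <- function(x, is_a, ridge) {
  m1 <- colMeans(x[is_a, , drop = FALSE])
  m2 <- colMeans(x[!is_a, , drop = FALSE])
  dm <- m1 - m2
  if (ncol(x) == 1) return(abs(dm))  # degenerate 1-D case
  c1 <- stats::cov(x[is_a, , drop = FALSE])
  c2 <- stats::cov(x[!is_a, , drop = FALSE])
  n1 <- sum(is_a); n2 <- sum(!is_a)
  sw <- ((n1 - 1) * c1 + (n2 - 1) * c2) / max(n1 + n2 - 2, 1)
  lam <- ridge * (mean(diag(sw)) + 1)
  w <- NULL
  for (i in 0:8) {   # grow the ridge if the system is still singular
    w <- tryCatch(solve(sw + lam * 10^i * diag(ncol(x)), dm),
                  error = function(e) NULL)
    if (!is.null(w)) break
  }
  if (is.null(w)) return(abs(dm))
  wn <- sqrt(sum(w^2))
  if (wn == 0) return(abs(dm))
  w_unit <- w / wn
  proj_diff <- abs(sum(w_unit * dm))
  (abs(dm) + abs(w_unit) * proj_diff) / 2
}

#' Bootstrapped LDA effect sizes (LEfSe stage 2)
#'
#' Relative abundances are scaled to a per-million basis; on each of
#' `n_bootstrap` stratified subsamples (`subsample_frac` of each group) a
#' ridge-regularized Fisher linear discriminant is fitted over the passing
#' taxa, and each taxon's effect blends its raw scaled class-mean
#' difference with its share of the discriminant-projected difference (the
#' average of the two, as in canonical LEfSe). The score is log10 of the
#' bootstrap-mean effect, so the conventional "LDA > 2" threshold means a
#' class-mean difference around 100 parts per million. With more than two
#' groups each group is contrasted one-vs-rest and a taxon's score is its
#' maximum over contrasts; the enriched group is the one with the highest
#' mean relative abundance.
#'
#' @param table an [otu_table].
#' @param groups group label per sample.
#' @param taxa taxa to score (normally the Kruskal-Wallis pass set).
#' @param n_bootstrap bootstrap rounds (default 30).
#' @param subsample_frac per-group subsampling fraction (default 2/3).
#' @param seed integer seed; scores are deterministic under it.
#' @param ridge relative ridge on the pooled covariance (default 1e-6).
#' @return data.frame: taxon, lda_score, enriched_group.
#' @export
lda_effect_size <- function(table, groups, taxa, n_bootstrap = 30,
                            subsample_frac = 2 / 3, seed = 1L,
                            ridge = 1e-6) {
  stopifnot_otu_table(table)
  groups <- as.character(groups)
  if (!length(taxa)) stop("empty taxa set")
  if (!all(taxa %in% otu_ids(table)))
    stop("unknown taxa: ", paste(setdiff(taxa, otu_ids(table)),
                                 collapse = ", "))
  taxa_in <- taxa
  taxa <- sort(unique(taxa))
  ra <- relative_abundance(table)[, taxa, drop = FALSE] * 1e6
  # canonical sample order makes scores invariant to row permutations
  ord <- order(rownames(ra))
  ra <- ra[ord, , drop = FALSE]
  g <- factor(groups[ord])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  contrasts <- if (nlevels(g) == 2) levels(g)[1] else levels(g)
  eff <- matrix(0, length(taxa), length(contrasts),
                dimnames = list(taxa, contrasts))
  for (ci in seq_along(contrasts)) {
    acc <- matrix(NA_real_, n_bootstrap, length(taxa))
    for (b in seq_len(n_bootstrap)) {
      for (try in 1:25) {
        idx <- lefse_subsample(g, subsample_frac)
        is_a <- g[idx] == contrasts[ci]
        if (any(is_a) && any(!is_a)) break
        if (try == 25) stop("could not draw a two-class bootstrap sample")
      }
      acc[b, ] <- lda_contrast_effect(ra[idx, , drop = FALSE], is_a, ridge)
    }
    eff[, ci] <- colMeans(acc)
  }
  group_means <- apply(ra, 2, function(x) tapply(x, g, mean))
  out <- data.frame(taxon = taxa,
                    lda_score = log10(pmax(apply(eff, 1, max), 1e-10)),
                    enriched_group =
                      levels(g)[apply(group_means, 2, which.max)],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[match(taxa_in, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LEfSe-style differential abundance
#'
#' Full two-stage workflow: Kruskal-Wallis screen at `alpha`, then
#' bootstrapped LDA effect sizes for the passing taxa. A taxon is
#' significant when both its screen p-value < `alpha` and its LDA score >
#' `lda_min` (the conventional thresholds are 0.05 and 2). Taxa failing
#' the screen are reported with an `NA` score.
#'
#' @inheritParams lda_effect_size
#' @param alpha screening level (default 0.05).
#' @param lda_min log10 effect-size threshold (default 2).
#' @return data.frame: taxon, kruskal_wallis_p, lda_score, enriched_group,
#'   significant.
#' @export
lefse <- function(table, groups, alpha = 0.05, lda_min = 2,
                  n_bootstrap = 30, subsample_frac = 2 / 3, seed = 1L,
                  ridge = 1e-6) {
  screen <- kruskal_wallis_screen(table, groups, alpha)
  out <- data.frame(taxon = screen$taxon,
                    kruskal_wallis_p = screen$p_value,
                    lda_score = NA_real_,
                    enriched_group = NA_character_,
                    significant = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  pass <- screen$taxon[screen$pass]
  if (length(pass)) {
    scores <- lda_effect_size(table, groups, pass,
                              n_bootstrap = n_bootstrap,
                              subsample_frac = subsample_frac,
                              seed = seed, ridge = ridge)
    i <- match(scores$taxon, out$taxon)
    out$lda_score[i] <- scores$lda_score
    out$enriched_group[i] <- scores$enriched_group
    out$significant[i] <- out$kruskal_wallis_p[i] < alpha &
      scores$lda_score > lda_min
  }
  out
}

#' Collapse an OTU table by a taxonomy rank
#'
#' Sums counts of OTUs sharing the same lineage prefix at the given rank
#' (1 = phylum ... 6 = genus, 7 = species, for the usual seven-rank
#' lineages). OTUs without taxonomy, or with an empty field at that rank,
#' keep their own id — stages that report names degrade gracefully to OTU
#' ids.
#'
#' @param table an [otu_table] with (partial) taxonomy.
#' @param rank lineage field index to collapse at (default 6, genus).
#' @return an [otu_table] whose columns are taxa at the requested rank.
#' @export
aggregate_taxonomy <- function(table, rank = 6) {
  stopifnot_otu_table(table)
  ids <- otu_ids(table)
  label <- ids
  if (!is.null(table$taxonomy)) {
    tx <- table$taxonomy[ids]
    fields <- strsplit(ifelse(is.na(tx), "", tx), ";")
    at <- vapply(fields, function(f)
      if (length(f) >= rank && nzchar(trimws(f[rank]))) trimws(f[rank])
      else "", character(1))
    label[nzchar(at)] <- at[nzchar(at)]
  }
  agg <- t(rowsum(t(table$counts), group = label))
  otu_table(agg[, order(colnames(agg)), drop = FALSE])
}
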