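#' Thresholds of the three-criterion core-community rule
#'
#' A core OTU must (1) have dataset-mean relative abundance strictly above
#' `mean_ra_min`, (2) be detected (count >= 1) in strictly more than
#' `occupancy_min` of the samples, and (3) be "abundant" — among the OTUs
#' making up the top `abundant_cumulative` share of a sample's reads — in
#' at least `abundant_sample_frac_min` of the samples. Criteria 1 and 2 are
#' strict (`>`), criterion 3 non-strict (`>=`), mirroring the "more than"
#' vs "at least" wording they encode.
#'
#' Criterion 1 is deliberately the dataset-wide mean (not ">1% in every
#' sample"): reported core taxa routinely carry standard deviations larger
#' than their means, which the every-sample reading cannot produce. The
#' literal reading is available via `strict_every_sample` in
#' [select_core()].
#'
#' @param mean_ra_min minimum dataset-mean relative abundance (default 1%).
#' @param occupancy_min minimum occupancy fraction (default 80%).
#' @param abundant_cumulative per-sample cumulative read share defining
#'   "abundant" (default 80%).
#' @param abundant_sample_frac_min minimum fraction of samples in which the
#'   OTU must be abundant (default 50%).
#' @return a `core_criteria` list.
#' @export
core_criteria <- function(mean_ra_min = 0.01, occupancy_min = 0.8,
                          abundant_cumulative = 0.8,
                          abundant_sample_frac_min = 0.5) {
  x <- list(mean_ra_min = mean_ra_min, occupancy_min = occupancy_min,
            abundant_cumulative = abundant_cumulative,
            abundant_sample_frac_min = abundant_sample_frac_min)
  if (any(unlist(x) <= 0) || any(unlist(x) > 1))
    stop("all criteria must lie in (0, 1]")
  structure(x, class = "core_criteria")
}

#' Cumulative rank-abundance curve
#'
#' For each sample, OTUs are sorted by decreasing count and the cumulative
#' read proportion is taken at each rank; ranks are then aggregated across
#' samples as mean and sd. This is the curve on which "the OTUs comprising
#' the top 80% of reads" is read off.
#'
#' @param table an [otu_table].
#' @return data.frame with columns rank, mean, sd.
#' @export
cumulative_rank_curve <- function(table) {
  stopifnot_otu_table(table)
  ra <- relative_abundance(table)
  cum <- t(apply(ra, 1, function(p) cumsum(sort(p, decreasing = TRUE))))
  data.frame(rank = seq_len(ncol(cum)),
             mean = colMeans(cum),
             sd = apply(cum, 2, stats::sd))
}

#' Abundant OTUs of one sample
#'
#' The smallest prefix of the OTUs, sorted by decreasing count, whose
#' cumulative read proportion reaches `abundant_cumulative`; the OTU that
#' crosses the boundary is included. Ties at a rank boundary are broken by
#' lexicographic OTU id so membership is deterministic.
#'
#' @param counts named non-negative count vector (one sample).
#' @param abundant_cumulative cumulative share threshold (default 0.8).
#' @return character vector of abundant OTU ids.
#' @export
abundant_otus <- function(counts, abundant_cumulative = 0.8) {
  if (sum(counts) == 0) stop("sample has zero total reads")
  if (is.null(names(counts)))
    names(counts) <- paste0("OTU", seq_along(counts))
  ord <- order(-counts, names(counts), method = "radix")
  cum <- cumsum(counts[ord]) / sum(counts)
  k <- which(cum >= abundant_cumulative - 1e-12)[1]
  names(counts)[ord[seq_len(k)]]
}

#' Per-OTU occupancy
#'
#' Fraction of samples in which each OTU is detected (count >= 1).
#'
#' @param table an [otu_table].
#' @return named numeric vector in `[0, 1]`.
#' @export
occupancy <- function(table) {
  stopifnot_otu_table(table)
  colMeans(table$counts >= 1)
}

#' Occupancy-abundance bins
#'
#' Classifies OTUs into right-closed occupancy bins ((0,5%], (5,10%], ...,
#' by default; occupancy 0 falls in the first bin) and reports per bin the
#' number of OTUs and their summed dataset-mean relative abundance. The bin
#' counts sum to the number of OTUs and the abundances to 1.
#'
#' @param table an [otu_table].
#' @param bin_width occupancy bin width; must divide 1 evenly.
#' @return data.frame with columns bin_low, bin_high, n_otus,
#'   relative_abundance.
#' @export
occupancy_abundance_bins <- function(table, bin_width = 0.05) {
  stopifnot_otu_table(table)
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1 evenly")
  nb <- round(nb)
  occ <- occupancy(table)
  mean_ra <- colMeans(relative_abundance(table))
  # occupancies are k/n rationals; round before ceiling so exact bin
  # boundaries (e.g. 0.9 / 0.05) do not spill into the next bin
  bin <- pmin(pmax(ceiling(round(occ / bin_width, 9)), 1), nb)
  data.frame(
    bin_low = round((seq_len(nb) - 1) * bin_width, 10),
    bin_high = round(seq_len(nb) * bin_width, 10),
    n_otus = vapply(seq_len(nb), function(b) sum(bin == b), numeric(1)),
    relative_abundance = vapply(seq_len(nb), function(b)
      sum(mean_ra[bin == b]), numeric(1)))
}

#' Select the core community
#'
#' Applies the three-criterion rule of [core_criteria()] to every OTU and
#' summarizes the core: number and percentage of core OTUs, and the mean
#' and sd across samples of the summed core relative abundance (the "core
#' share"). An empty core is a valid result, not an error.
#'
#' @param table an [otu_table] with at least 2 samples.
#' @param criteria a [core_criteria()].
#' @param strict_every_sample if `TRUE`, criterion 1 becomes "relative
#'   abundance > mean_ra_min in every sample" (the literal wording).
#' @return list of class `core_community`: `evidence` data.frame (per OTU:
#'   mean_relative_abundance, occupancy_fraction, abundant_fraction,
#'   is_core), and `summary` (n_core, core_pct_of_otus, core_share_mean,
#'   core_share_sd, per_sample_core_share).
#' @export
select_core <- function(table, criteria = core_criteria(),
                        strict_every_sample = FALSE) {
  stopifnot_otu_table(table)
  if (!inherits(criteria, "core_criteria"))
    criteria <- do.call(core_criteria, criteria)
  if (n_samples(table) < 2) stop("core selection needs >= 2 samples")
  ra <- relative_abundance(table)
  mean_ra <- colMeans(ra)
  occ <- occupancy(table)
  abund <- matrix(FALSE, n_samples(table), n_otus(table),
                  dimnames = dimnames(table$counts))
  for (s in seq_len(n_samples(table))) {
    x <- stats::setNames(table$counts[s, ], otu_ids(table))
    ids <- abundant_otus(x, criteria$abundant_cumulative)
    abund[s, ids] <- TRUE
  }
  abundant_frac <- colMeans(abund)
  crit1 <- if (strict_every_sample)
    apply(ra > criteria$mean_ra_min, 2, all) else
      mean_ra > criteria$mean_ra_min
  is_core <- crit1 & occ > criteria$occupancy_min &
    abundant_frac >= criteria$abundant_sample_frac_min
  share <- if (any(is_core))
    rowSums(ra[, is_core, drop = FALSE]) else
      stats::setNames(rep(0, n_samples(table)), sample_ids(table))
  structure(list(
    evidence = data.frame(otu_id = otu_ids(table),
                          mean_relative_abundance = unname(mean_ra),
                          occupancy_fraction = unname(occ),
                          abundant_fraction = unname(abundant_frac),
                          is_core = unname(is_core),
                          row.names = NULL, stringsAsFactors = FALSE),
    summary = list(n_core = sum(is_core),
                   core_pct_of_otus = 100 * sum(is_core) / n_otus(table),
                   core_share_mean = mean(share),
                   core_share_sd = stats::sd(share),
                   per_sample_core_share = share),
    criteria = criteria), class = "core_community")
}

#' @export
print.core_community <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "core community: %d OTUs (%.2f%% of OTUs), share %.2f%% (+/- %.2f%%)\n",
    s$n_core, s$core_pct_of_otus, 100 * s$core_share_mean,
    100 * s$core_share_sd))
  invisible(x)
}

#' @rdname select_core
#' @return for `core_otu_ids`: character vector of core OTU ids.
#' @param core a `core_community` result.
#' @export
core_otu_ids <- function(core) core$evidence$otu_id[core$evidence$is_core]

#' Per-group core communities
#'
#' Applies [select_core()] independently to each group's sample subset
#' (e.g. provincial cores). Groups with fewer than 2 samples are skipped
#' with a warning. The national core need not be a subset of any group
#' core, nor vice versa.
#'
#' @param table an [otu_table].
#' @param metadata metadata data.frame with `sample_id` and `group`.
#' @param criteria a [core_criteria()].
#' @param strict_every_sample see [select_core()].
#' @return named list of `core_community` results, one per retained group.
#' @export
per_group_core <- function(table, metadata, criteria = core_criteria(),
                           strict_every_sample = FALSE) {
  stopifnot_otu_table(table)
  metadata <- validate_metadata_lite(metadata)
  ids <- sample_ids(table)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  grp <- metadata$group[match(ids, metadata$sample_id)]
  out <- list()
  for (g in unique(grp)) {
    sub <- ids[grp == g]
    if (length(sub) < 2) {
      warning("group '", g, "' has < 2 samples; skipped")
      next
    }
    out[[g]] <- select_core(filter_samples(table, sub), criteria,
                            strict_every_sample)
  }
  out
}

# group-only validation: MRPP/core stages need sample_id + group but not
# the environmental covariates
validate_metadata_lite <- function(metadata) {
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata needs columns sample_id and group")
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  metadata
}
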