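#' Configuration for the synthetic leaf-community generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' per-OTU latent mean abundances drawn from a lognormal (so observed counts
#' have zero-truncated Poisson-lognormal marginals), a planted core of
#' simultaneously abundant and ubiquitous OTUs, province-structured
#' composition with group-specific differential taxa, environmental
#' covariates drawn around group-specific centers that can optionally drive
#' a log-linear composition gradient, and a random bifurcating phylogeny.
#'
#' Defaults mirror the motivating study at desk scale: the eight province
#' codes, ~10 samples per group, a mean sequencing depth of 12000 reads
#' (945434 reads / 78 samples in the study), 1000 OTUs (scaled down from
#' 4473) and 14 planted core OTUs.
#'
#' @param groups character vector of group (province) labels.
#' @param n_samples_per_group samples per group (recycled over groups).
#' @param n_otus total number of OTUs.
#' @param sad_mu,sad_sigma log-mean and log-sd of the latent lognormal OTU
#'   abundance; `sad_sigma` controls community unevenness.
#' @param depth_mean expected total reads per sample.
#' @param n_core number of planted core OTUs. The core is planted on the
#'   `n_core` largest latent abundances and then multiplied by `core_boost`:
#'   core taxa are by definition the dominant, ubiquitous fraction.
#' @param core_boost multiplicative abundance factor (> 1) for core OTUs.
#' @param core_occupancy per-sample presence probability for core OTUs.
#' @param background_occupancy presence probability for non-core OTUs.
#' @param differential optional data.frame with columns `otu` (index or id),
#'   `group`, `fold` (> 0): multiplies that OTU's latent abundance in that
#'   group. An optional `occupancy` column overrides the OTU's presence
#'   probability (in all samples), so differential taxa can be made
#'   detectable rather than inheriting the sparse background occupancy.
#' @param env_effect optional list `list(covariate = <name>, strength = s)`;
#'   OTU latent abundances are tilted log-linearly in the standardized
#'   covariate with per-OTU loadings ~ N(0, strength^2).
#' @param seed integer root seed; identical config + seed gives
#'   bit-identical output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(groups = c("YN", "HeN", "CQ", "HuN",
                                        "GZ", "SC", "HLJ", "FJ"),
                             n_samples_per_group = 10,
                             n_otus = 1000,
                             sad_mu = 1, sad_sigma = 1.5,
                             depth_mean = 12000,
                             n_core = 14, core_boost = 20,
                             core_occupancy = 0.95,
                             background_occupancy = 0.3,
                             differential = NULL,
                             env_effect = NULL,
                             seed = 1L) {
  cfg <- list(groups = as.character(groups),
              n_samples_per_group =
                rep_len(as.integer(n_samples_per_group), length(groups)),
              n_otus = as.integer(n_otus),
              sad_mu = sad_mu, sad_sigma = sad_sigma,
              depth_mean = depth_mean,
              n_core = as.integer(n_core), core_boost = core_boost,
              core_occupancy = core_occupancy,
              background_occupancy = background_occupancy,
              differential = differential, env_effect = env_effect,
              seed = as.integer(seed))
  if (cfg$n_core > cfg$n_otus) stop("config error: n_core > n_otus")
  if (cfg$n_core < 0 || cfg$n_otus < 1) stop("config error: sizes")
  if (any(cfg$n_samples_per_group < 1)) stop("config error: sample sizes")
  if (cfg$core_occupancy <= 0 || cfg$core_occupancy > 1 ||
      cfg$background_occupancy <= 0 || cfg$background_occupancy > 1)
    stop("config error: occupancies must lie in (0, 1]")
  if (cfg$depth_mean <= 0) stop("config error: depth_mean must be > 0")
  if (cfg$core_boost <= 0) stop("config error: core_boost must be > 0")
  if (cfg$sad_sigma < 0) stop("config error: sad_sigma must be >= 0")
  if (!is.null(differential)) {
    if (!all(c("otu", "group", "fold") %in% names(differential)))
      stop("config error: differential needs columns otu, group, fold")
    if (any(differential$fold <= 0))
      stop("config error: fold-changes must be > 0")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# approximate geographic/climatic centers for the eight province codes;
# unknown labels get centers drawn once from these ranges
.province_centers <- data.frame(
  group = c("YN", "HeN", "CQ", "HuN", "GZ", "SC", "HLJ", "FJ"),
  longitude = c(102.7, 113.6, 106.5, 112.9, 106.7, 104.1, 126.6, 119.3),
  latitude = c(25.0, 34.7, 29.5, 28.2, 26.6, 30.6, 45.8, 26.1),
  altitude = c(1890, 110, 400, 100, 1100, 500, 150, 200),
  temperature = c(16.5, 14.5, 18.5, 17.5, 15.0, 16.5, 4.0, 20.0),
  precipitation = c(990, 650, 1100, 1400, 1150, 1000, 550, 1400),
  stringsAsFactors = FALSE)

#' Generate a synthetic dataset
#'
#' Draws, in a fixed order under one root seed: latent OTU abundances
#' lambda_i ~ Lognormal(sad_mu, sad_sigma); plants the core on the `n_core`
#' largest lambda (boosted by `core_boost`); applies group fold-changes and
#' the optional environmental tilt; per sample masks each OTU by a Bernoulli
#' presence draw (core vs background occupancy) and draws counts ~
#' Poisson(depth_mean * masked lambda / sum(masked lambda)), so row totals
#' concentrate at `depth_mean`; draws covariates around group centers and a
#' random bifurcating tree with Exp(1) branch lengths.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with `table` ([otu_table]),
#'   `metadata` (data.frame), `tree` (`phylo`), and `truth` (planted core
#'   ids, differential taxa, latent lambda, per-OTU occupancy probability).
#' @export
synthesize_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n_otus <- config$n_otus
  otu_id <- sprintf("OTU_%04d", seq_len(n_otus))
  lambda <- stats::rlnorm(n_otus, config$sad_mu, config$sad_sigma)
  core_idx <- if (config$n_core > 0)
    order(lambda, decreasing = TRUE)[seq_len(config$n_core)] else integer(0)
  lambda_boost <- lambda
  lambda_boost[core_idx] <- lambda_boost[core_idx] * config$core_boost

  groups <- rep(config$groups, config$n_samples_per_group)
  n_samples <- length(groups)
  sid <- sprintf("%s_%02d", groups, stats::ave(seq_len(n_samples), groups,
                                               FUN = seq_along))

  covs <- c("longitude", "latitude", "altitude", "temperature",
            "precipitation")
  jitter_sd <- c(longitude = 1, latitude = 1, altitude = 100,
                 temperature = 1, precipitation = 80)
  centers <- .province_centers[match(config$groups,
                                     .province_centers$group), covs]
  rownames(centers) <- config$groups
  for (g in which(is.na(centers$longitude))) {  # unknown labels
    centers[g, ] <- c(stats::runif(1, 90, 130), stats::runif(1, 20, 50),
                      stats::runif(1, 50, 2000), stats::runif(1, 2, 22),
                      stats::runif(1, 400, 1600))
  }
  metadata <- data.frame(sample_id = sid, group = groups,
                         stringsAsFactors = FALSE)
  for (v in covs)
    metadata[[v]] <- centers[groups, v] +
      stats::rnorm(n_samples, 0, jitter_sd[[v]])

  env_load <- NULL
  if (!is.null(config$env_effect)) {
    ev <- config$env_effect
    if (!ev$covariate %in% covs)
      stop("config error: unknown env_effect covariate '", ev$covariate, "'")
    env_load <- stats::rnorm(n_otus, 0, ev$strength)
    z <- metadata[[ev$covariate]]
    z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  }

  diff_idx <- NULL
  if (!is.null(config$differential)) {
    d <- config$differential
    idx <- if (is.numeric(d$otu)) as.integer(d$otu) else match(d$otu, otu_id)
    if (any(is.na(idx)) || any(idx < 1 | idx > n_otus))
      stop("config error: differential refers to unknown OTUs")
    if (any(!d$group %in% config$groups))
      stop("config error: differential refers to unknown groups")
    diff_idx <- data.frame(otu = idx, group = as.character(d$group),
                           fold = d$fold, stringsAsFactors = FALSE)
  }

  occ_prob <- ifelse(seq_len(n_otus) %in% core_idx,
                     config$core_occupancy, config$background_occupancy)
  if (!is.null(diff_idx) && !is.null(config$differential$occupancy)) {
    ov <- config$differential$occupancy
    if (any(ov <= 0 | ov > 1))
      stop("config error: occupancy overrides must lie in (0, 1]")
    occ_prob[diff_idx$otu] <- ov
  }
  counts <- matrix(0, n_samples, n_otus, dimnames = list(sid, otu_id))
  for (s in seq_len(n_samples)) {
    lam <- lambda_boost
    if (!is.null(diff_idx)) {
      rows <- diff_idx$group == groups[s]
      if (any(rows))
        lam[diff_idx$otu[rows]] <- lam[diff_idx$otu[rows]] *
          diff_idx$fold[rows]
    }
    if (!is.null(env_load)) lam <- lam * exp(env_load * z[s])
    present <- stats::runif(n_otus) < occ_prob
    lam <- lam * present
    tot <- sum(lam)
    if (tot == 0) { # pathological mask: keep the sample non-empty
      lam[which.max(lambda_boost)] <- lambda_boost[which.max(lambda_boost)]
      tot <- sum(lam)
    }
    counts[s, ] <- stats::rpois(n_otus, config$depth_mean * lam / tot)
  }
  # a sample with zero reads would be invalid; at realistic depths this is
  # unreachable, but guard for tiny configs
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, which.max(colMeans(counts))] <- 1

  tree <- random_phylo(n_otus, labels = otu_id)

  structure(list(
    table = otu_table(counts),
    metadata = metadata,
    tree = tree,
    truth = list(core_otus = otu_id[core_idx],
                 differential = if (is.null(diff_idx)) NULL else
                   transform(diff_idx, otu = otu_id[diff_idx$otu]),
                 lambda = stats::setNames(lambda_boost, otu_id),
                 occupancy_prob = stats::setNames(occ_prob, otu_id),
                 env_loadings = if (is.null(env_load)) NULL else
                   stats::setNames(env_load, otu_id)),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d samples x %d OTUs, %d groups, %d planted core\n",
    n_samples(x$table), n_otus(x$table), length(unique(x$metadata$group)),
    length(x$truth$core_otus)))
  invisible(x)
}

#' Random rooted bifurcating phylogeny
#'
#' Topology from [ape::rtree()] with Exp(1) branch lengths; used to exercise
#' the UniFrac stage without real sequences. Drawn from the current RNG
#' state unless `seed` is given.
#'
#' @param n_tips number of tips (>= 1).
#' @param labels tip labels (default `t1..tn`).
#' @param seed optional integer seed for a self-contained reproducible draw.
#' @return a rooted `phylo` with `n_tips` tips.
#' @export
random_phylo <- function(n_tips, labels = NULL, seed = NULL) {
  if (n_tips < 1) stop("n_tips must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  if (n_tips == 1)
    return(validate_tree(ape::read.tree(
      text = sprintf("(%s:%.10f);", labels[1], stats::rexp(1)))))
  tree <- ape::rtree(n_tips, br = stats::rexp)
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  validate_tree(tree)
}
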