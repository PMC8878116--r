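#' Redundancy analysis of community composition on environmental factors
#'
#' Constrained ordination: the (transformed) community matrix is regressed
#' on the standardized explanatory factors and the fitted values are
#' ordinated (via [vegan::rda()]). Each factor gets a marginal permutation
#' test — the factor against the model containing all the others, by
#' residual permutation under the reduced model ([vegan::anova.cca()] with
#' `by = "margin"`) — and is flagged significant when -log10(p) > 1.3. All
#' permutations are enumerated exhaustively when the sample count is at
#' most 7.
#'
#' `rda_env` is the table-level interface; `rda_fit` accepts an arbitrary
#' numeric response matrix (used for simulation checks and non-count
#' responses).
#'
#' @param table an [otu_table].
#' @param metadata metadata data.frame (see [read_sample_metadata()]).
#' @param factors explanatory column names (default the five environmental
#'   covariates).
#' @param transform `"hellinger"` (default; square root of relative
#'   abundances, the standard guard against the double-zero problem),
#'   `"relative"`, or `"none"` (raw counts).
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed integer seed; permutation p-values are deterministic under it.
#' @return list of class `rda_result`: `site_scores`, `biplot_scores`,
#'   `eigenvalues` (constrained), `proportion_constrained`,
#'   `proportion_unconstrained`, `axis_proportion` (per constrained axis,
#'   share of constrained variance), and `factor_tests` (data.frame:
#'   factor, F, p_value, neg_log10_p, significant).
#' @export
rda_env <- function(table, metadata,
                    factors = c("longitude", "latitude", "altitude",
                                "temperature", "precipitation"),
                    transform = c("hellinger", "relative", "none"),
                    n_permutations = 999, seed = 1L) {
  stopifnot_otu_table(table)
  transform <- match.arg(transform)
  metadata <- validate_metadata_lite(metadata)
  ids <- sample_ids(table)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  missing <- setdiff(factors, names(metadata))
  if (length(missing))
    stop("metadata missing factor column(s): ",
         paste(missing, collapse = ", "))
  x <- metadata[match(ids, metadata$sample_id), factors, drop = FALSE]
  if (any(!is.finite(as.matrix(x)))) stop("non-finite factor values")
  y <- switch(transform,
              hellinger = sqrt(relative_abundance(table)),
              relative = relative_abundance(table),
              none = table$counts)
  rda_fit(y, x, n_permutations = n_permutations, seed = seed)
}

#' @rdname rda_env
#' @param response numeric samples x variables response matrix.
#' @param explanatory numeric samples x factors data.frame or matrix.
#' @export
rda_fit <- function(response, explanatory, n_permutations = 999,
                    seed = 1L) {
  y <- as.matrix(response)
  x <- as.data.frame(explanatory)
  if (nrow(y) != nrow(x)) stop("response/explanatory row mismatch")
  if (nrow(y) < ncol(x) + 2)
    stop("need at least 2 more samples than factors")
  xs <- scale(as.matrix(x))
  if (any(!is.finite(xs)))
    stop("constant factor column(s): ",
         paste(colnames(x)[apply(as.matrix(x), 2, stats::sd) == 0],
               collapse = ", "))
  sv <- svd(xs)$d
  if (min(sv) == 0 || max(sv) / min(sv) > 1e8) {
    qrx <- qr(xs)
    dep <- colnames(xs)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("collinear factor set (condition number > 1e8): ",
         paste(dep, collapse = ", "))
  }
  xs <- as.data.frame(xs)
  m <- suppressMessages(vegan::rda(y ~ ., data = xs))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perms <- if (nrow(y) <= 7) as.matrix(permute::allPerms(nrow(y)))
  else n_permutations
  aov <- tryCatch(
    suppressWarnings(vegan::anova.cca(m, by = "margin",
                                      permutations = perms)),
    error = function(e) NULL)
  idx <- if (is.null(aov)) integer(0) else
    match(colnames(xs), rownames(aov))
  ft <- data.frame(factor = colnames(xs),
                   F = if (is.null(aov)) NA_real_ else aov$F[idx],
                   p_value = if (is.null(aov)) NA_real_ else
                     aov$`Pr(>F)`[idx],
                   stringsAsFactors = FALSE)
  ft$neg_log10_p <- -log10(ft$p_value)
  ft$significant <- !is.na(ft$p_value) & ft$neg_log10_p > 1.3
  eig <- m$CCA$eig
  structure(list(
    site_scores = vegan::scores(m, display = "sites",
                                choices = seq_along(eig)),
    biplot_scores = vegan::scores(m, display = "bp",
                                  choices = seq_along(eig)),
    eigenvalues = eig,
    proportion_constrained = m$CCA$tot.chi / m$tot.chi,
    proportion_unconstrained = m$CA$tot.chi / m$tot.chi,
    axis_proportion = eig / sum(eig),
    factor_tests = ft,
    model = m), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: %.1f%% of variance constrained\n",
              100 * x$proportion_constrained))
  print(x$factor_tests, digits = 4)
  invisible(x)
}

#' Latitudinal (and longitudinal) diversity gradient
#'
#' Spearman rank correlation of a per-sample diversity index against
#' latitude and longitude, with two-sided p-values. A constant covariate
#' yields an undefined-correlation flag rather than an error.
#'
#' @param table an [otu_table].
#' @param metadata metadata with `latitude` and `longitude`.
#' @param index per-sample index function (default [shannon_index()]).
#' @return data.frame: covariate, rho, p_value, undefined.
#' @export
latitudinal_gradient <- function(table, metadata, index = shannon_index) {
  stopifnot_otu_table(table)
  ids <- sample_ids(table)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), ]
  div <- apply(table$counts, 1, index)
  rows <- lapply(c("latitude", "longitude"), function(v) {
    z <- md[[v]]
    if (stats::sd(z) == 0 || stats::sd(div) == 0)
      return(data.frame(covariate = v, rho = NA_real_, p_value = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(div, z, method = "spearman"))
    data.frame(covariate = v, rho = unname(ct$estimate),
               p_value = ct$p.value, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
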