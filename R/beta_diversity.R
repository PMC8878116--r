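#' @importFrom stats setNames
NULL

# edges x tips incidence of a rooted tree: row e is TRUE for tips descending
# through edge e. Built once per tree by postorder accumulation.
edge_tip_incidence <- function(tree) {
  validate_tree(tree)
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(tr$edge)
  desc <- matrix(FALSE, nt + tr$Nnode, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(ne)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  inc <- desc[tr$edge[, 2], , drop = FALSE]
  colnames(inc) <- tr$tip.label
  list(incidence = inc, lengths = tr$edge.length)
}

check_tree_cover <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from tree: ", paste(missing, collapse = ", "))
}

#' Unweighted UniFrac distance between two presence sets
#'
#' The fraction of observed branch length unique to one of the two
#' communities: sum of lengths of branches leading exclusively to taxa of
#' one sample, divided by the summed length of branches leading to taxa of
#' either sample. A branch is "observed" only when at least one descendant
#' taxon is present in either sample; the root carries no branch.
#'
#' @param tree rooted `phylo` with branch lengths; all taxa must be tips.
#' @param taxa1,taxa2 character vectors of present OTU ids (non-empty).
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, taxa1, taxa2) {
  if (!length(taxa1) || !length(taxa2))
    stop("each sample needs at least one present OTU")
  check_tree_cover(tree, union(taxa1, taxa2))
  et <- edge_tip_incidence(tree)
  a <- et$incidence[, colnames(et$incidence) %in% taxa1,
                    drop = FALSE] |> rowSums() > 0
  b <- et$incidence[, colnames(et$incidence) %in% taxa2,
                    drop = FALSE] |> rowSums() > 0
  denom <- sum(et$lengths[a | b])
  if (denom == 0) return(0)
  sum(et$lengths[xor(a, b)]) / denom
}

#' Weighted UniFrac distance between two abundance profiles
#'
#' sum_b L_b |p_b1 - p_b2| where p_bs is the fraction of sample s's
#' abundance descending through branch b; the normalized form (default)
#' divides by sum_b L_b (p_b1 + p_b2), bounding the distance in `[0, 1]`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param abund1,abund2 named non-negative abundance vectors (normalized to
#'   proportions internally).
#' @param normalized return the normalized (bounded) form.
#' @return non-negative distance (`[0, 1]` when normalized).
#' @export
weighted_unifrac <- function(tree, abund1, abund2, normalized = TRUE) {
  if (sum(abund1) == 0 || sum(abund2) == 0)
    stop("each sample needs positive total abundance")
  check_tree_cover(tree, union(names(abund1)[abund1 > 0],
                               names(abund2)[abund2 > 0]))
  et <- edge_tip_incidence(tree)
  p <- function(ab) {
    ab <- ab / sum(ab)
    v <- setNames(rep(0, ncol(et$incidence)), colnames(et$incidence))
    v[names(ab)[names(ab) %in% names(v)]] <- ab[names(ab) %in% names(v)]
    as.numeric(et$incidence %*% v)
  }
  p1 <- p(abund1); p2 <- p(abund2)
  num <- sum(et$lengths * abs(p1 - p2))
  if (!normalized) return(num)
  den <- sum(et$lengths * (p1 + p2))
  if (den == 0) 0 else num / den
}

#' Sample-sample distance matrix
#'
#' All pairwise distances between the samples of a table under unweighted
#' UniFrac, weighted UniFrac (normalized) or Bray-Curtis (the tree-free
#' fallback, via [vegan::vegdist()]). Symmetry is exact and the diagonal
#' zero.
#'
#' @param table an [otu_table].
#' @param metric one of `"unweighted_unifrac"`, `"weighted_unifrac"`,
#'   `"bray_curtis"`.
#' @param tree rooted `phylo`; required for the UniFrac metrics.
#' @return object of class `dist_matrix`: square symmetric matrix with
#'   sample ids, attribute `metric`.
#' @export
distance_matrix <- function(table,
                            metric = c("unweighted_unifrac",
                                       "weighted_unifrac", "bray_curtis"),
                            tree = NULL) {
  stopifnot_otu_table(table)
  metric <- match.arg(metric)
  n <- n_samples(table)
  ids <- sample_ids(table)
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(table$counts, method = "bray"))
  } else {
    if (is.null(tree)) stop("a tree is required for UniFrac metrics")
    check_tree_cover(tree, otu_ids(table))
    et <- edge_tip_incidence(tree)
    m <- matrix(0, length(tree$tip.label), n,
                dimnames = list(colnames(et$incidence), ids))
    m[otu_ids(table), ] <- t(table$counts)
    if (metric == "unweighted_unifrac") {
      pres <- (et$incidence %*% (m > 0)) > 0   # edges x samples
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        obs <- pres[, i] | pres[, j]
        den <- sum(et$lengths[obs])
        d[i, j] <- d[j, i] <-
          if (den == 0) 0 else sum(et$lengths[xor(pres[, i],
                                                  pres[, j])]) / den
      }
    } else {
      prop <- et$incidence %*% sweep(m, 2, colSums(m), "/")
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        num <- sum(et$lengths * abs(prop[, i] - prop[, j]))
        den <- sum(et$lengths * (prop[, i] + prop[, j]))
        d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
      }
    }
    dimnames(d) <- list(ids, ids)
  }
  structure(d, metric = metric, class = c("dist_matrix", "matrix"))
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(diag(d) != 0) || any(d < 0))
    stop("expected a symmetric non-negative matrix with zero diagonal")
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition (via
#' [stats::cmdscale()]); coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Axes with negative eigenvalues are dropped
#' and reported, not corrected. On a Euclidean distance matrix the
#' embedding reproduces all pairwise distances.
#'
#' @param d square symmetric distance matrix (e.g. [distance_matrix()]).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (positive ones), `proportion` (share of the positive
#'   eigenvalue total per axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n == 1 || all(d == 0)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PCo1"))
    return(structure(list(coordinates = coords, eigenvalues = 0,
                          proportion = 0, negative_eigenvalues = numeric(0)),
                     class = "pcoa_result"))
  }
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- mds$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  coords <- mds$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = eig[pos],
                 proportion = eig[pos] / sum(eig[pos]),
                 negative_eigenvalues = eig[eig < -tol]),
            class = "pcoa_result")
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic means: iteratively merges
#' the closest pair of clusters; the distance between clusters is the
#' arithmetic mean of all between-member distances of the original matrix,
#' and the merge height is half that distance, so the tree is ultrametric.
#' Ties are broken by the lexicographic order of the clusters' smallest
#' member labels.
#'
#' @param d square symmetric distance matrix.
#' @return list of class `upgma_tree`: `merge` (hclust-style), `height`
#'   (merge heights, = d/2), `labels`, `newick` string.
#' @export
upgma <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("UPGMA needs >= 2 samples")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  members <- as.list(seq_len(n))           # original indices per cluster
  node_id <- as.integer(-seq_len(n))       # hclust convention
  minlab <- labels
  newick <- labels
  depth <- rep(0, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cd <- function(a, b) mean(d[members[[a]], members[[b]]])
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      dv <- cd(a, b)
      lab <- sort(c(minlab[a], minlab[b]))
      if (is.null(best) || dv < best$d - 1e-12 ||
          (abs(dv - best$d) <= 1e-12 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(a = a, b = b, d = dv, lab = lab)
      }
    }
    a <- best$a; b <- best$b
    h <- best$d / 2
    merge[step, ] <- c(node_id[a], node_id[b])
    height[step] <- h
    newick_ab <- sprintf("(%s:%.10g,%s:%.10g)",
                         newick[a], h - depth[a], newick[b], h - depth[b])
    members[[a]] <- c(members[[a]], members[[b]])
    node_id[a] <- step
    minlab[a] <- min(minlab[a], minlab[b])
    newick[a] <- newick_ab
    depth[a] <- h
    members[[b]] <- NULL
    node_id <- node_id[-b]; minlab <- minlab[-b]
    newick <- newick[-b]; depth <- depth[-b]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 newick = paste0(newick[1], ";")),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d samples, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

# all distinct assignments of group labels to positions, preserving group
# sizes; rows = assignments (as integer group codes)
enumerate_relabelings <- function(sizes) {
  n <- sum(sizes)
  out <- matrix(0L, 0, n)
  rec <- function(assigned, remaining_pos, g) {
    if (g > length(sizes)) {
      out <<- rbind(out, assigned)
      return(invisible())
    }
    picks <- if (length(remaining_pos) == sizes[g]) list(remaining_pos)
    else utils::combn(remaining_pos, sizes[g], simplify = FALSE)
    for (p in picks) {
      a <- assigned
      a[p] <- g
      rec(a, setdiff(remaining_pos, p), g + 1L)
    }
  }
  rec(integer(n), seq_len(n), 1L)
  out
}

n_relabelings <- function(sizes) {
  exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes)))
}

mrpp_delta <- function(d, codes, sizes) {
  n <- length(codes)
  delta <- 0
  for (g in seq_along(sizes)) {
    idx <- which(codes == g)
    sub <- d[idx, idx]
    delta <- delta + sizes[g] / n * mean(sub[upper.tri(sub)])
  }
  delta
}

#' Multi-response permutation procedure
#'
#' Tests whether within-group sample-sample distances are smaller than
#' expected under random relabeling. The observed statistic is delta =
#' sum_g (n_g / n) * (mean within-group distance of g). When the number of
#' distinct relabelings is at most `max_exhaustive` (and `exhaustive` is
#' not `FALSE`), all relabelings are enumerated and p is the exact fraction
#' with delta <= delta_obs; otherwise `n_permutations` random relabelings
#' are drawn and p uses the add-one estimator (never exactly 0). The
#' chance-corrected effect size is A = 1 - delta_obs / mean(delta_perm).
#' Significance is declared when -log10(p) > 1.3.
#'
#' @param d square symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed integer seed for the Monte-Carlo path.
#' @param exhaustive `"auto"` (default), `TRUE` or `FALSE`.
#' @param max_exhaustive enumeration cutoff (default 10000 relabelings).
#' @return list of class `mrpp_result`: delta_observed, expected_delta,
#'   A_statistic, p_value, neg_log10_p, significant, method, n_permutations.
#' @export
mrpp_test <- function(d, groups, n_permutations = 999, seed = 1L,
                      exhaustive = "auto", max_exhaustive = 10000) {
  d <- as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d))
    stop("groups length must match the distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("MRPP needs >= 2 groups")
  if (any(sizes < 2)) stop("every group needs >= 2 samples")
  codes <- as.integer(factor(groups, levels = names(sizes)))
  sizes <- as.integer(sizes)
  delta_obs <- mrpp_delta(d, codes, sizes)
  use_exhaustive <- if (identical(exhaustive, "auto"))
    n_relabelings(sizes) <= max_exhaustive else isTRUE(exhaustive)
  if (use_exhaustive) {
    lab <- enumerate_relabelings(sizes)
    deltas <- apply(lab, 1, mrpp_delta, d = d, sizes = sizes)
    p <- mean(deltas <= delta_obs + 1e-12)
    method <- "exhaustive"
    nperm <- nrow(lab)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    deltas <- vapply(seq_len(n_permutations), function(i)
      mrpp_delta(d, sample(codes), sizes), numeric(1))
    p <- (1 + sum(deltas <= delta_obs + 1e-12)) / (1 + n_permutations)
    method <- "permutation"
    nperm <- n_permutations
  }
  expected <- mean(deltas)
  structure(list(delta_observed = delta_obs, expected_delta = expected,
                 A_statistic = if (expected > 0) 1 - delta_obs / expected
                 else 0,
                 p_value = p, neg_log10_p = -log10(p),
                 significant = -log10(p) > 1.3,
                 method = method, n_permutations = nperm),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf(
    "MRPP (%s, %d relabelings): delta = %.4g, A = %.4g, p = %.4g%s\n",
    x$method, x$n_permutations, x$delta_observed, x$A_statistic, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise MRPP between all group pairs
#'
#' One [mrpp_test()] per unordered pair of groups, reported with
#' -log10(p). No multiplicity correction is applied by default; `p_adjust
#' = "BH"` switches to Benjamini-Hochberg adjusted p-values (the
#' significance flag then uses the adjusted values).
#'
#' @inheritParams mrpp_test
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per group pair: group1, group2, delta,
#'   A_statistic, p_value, neg_log10_p, significant.
#' @export
pairwise_mrpp <- function(d, groups, n_permutations = 999, seed = 1L,
                          exhaustive = "auto", p_adjust = c("none", "BH")) {
  d <- as_dist_matrix(d)
  p_adjust <- match.arg(p_adjust)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- groups %in% pr
    r <- mrpp_test(d[idx, idx, drop = FALSE], groups[idx],
                   n_permutations = n_permutations, seed = seed + k,
                   exhaustive = exhaustive)
    data.frame(group1 = pr[1], group2 = pr[2], delta = r$delta_observed,
               A_statistic = r$A_statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$neg_log10_p <- -log10(out$p_value)
  out$significant <- out$neg_log10_p > 1.3
  out
}
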