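#' Construct an OTU count table
#'
#' The central container of the package: a samples x OTUs matrix of
#' non-negative integer read counts, with unique sample and OTU identifiers
#' and an optional taxonomy map. Every downstream stage (core selection,
#' SAD fitting, diversity, ordination, differential abundance) consumes this
#' object.
#'
#' @param counts numeric matrix, one row per sample, one column per OTU;
#'   non-negative integers. Row and column names are used as sample and OTU
#'   identifiers; alternatively supply `sample_ids` / `otu_ids`.
#' @param sample_ids,otu_ids optional character vectors overriding dimnames.
#' @param taxonomy optional named character vector (or list) mapping OTU ids
#'   to semicolon-delimited ranked lineages; may cover only some OTUs.
#' @param require_positive_samples if `TRUE` (default) every sample must
#'   contain at least one read.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (named integer matrix), and `taxonomy` (named character vector or NULL).
#' @examples
#' tab <- otu_table(matrix(c(1, 2, 3, 4), 2, 2,
#'   dimnames = list(c("S1", "S2"), c("OTU1", "OTU2"))))
#' n_samples(tab)
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL,
                      taxonomy = NULL, require_positive_samples = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  counts <- round(counts)
  if (require_positive_samples && any(rowSums(counts) == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- unlist(taxonomy)
    if (is.null(names(taxonomy)))
      stop("taxonomy must be named by otu_id")
    extra <- setdiff(names(taxonomy), colnames(counts))
    if (length(extra))
      stop("taxonomy refers to unknown OTUs: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads%s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              if (is.null(x$taxonomy)) "" else
                sprintf(", taxonomy for %d OTUs", length(x$taxonomy))))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x$counts)

stopifnot_otu_table <- function(x) {
  if (!inherits(x, "otu_table")) stop("expected an otu_table")
  invisible(x)
}

#' Read an OTU table from disk
#'
#' Two dialects are supported. `"tsv"`: UTF-8 tab-separated, samples as
#' rows, OTUs as columns, first header cell `sample_id`. If a sidecar file
#' `<path>.taxonomy.tsv` exists (two columns, `otu_id` and a
#' semicolon-delimited lineage), it is attached automatically.
#' `"biom-json"`: dense BIOM v1 JSON (observations x samples, transposed on
#' read), parsed with the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param taxonomy_path optional explicit taxonomy sidecar path (tsv only).
#' @return a validated [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"),
                           taxonomy_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2 || names(df)[1] != "sample_id")
      stop("malformed header: first column must be 'sample_id'")
    counts <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(counts))
      stop("non-numeric count value in table")
    rownames(counts) <- as.character(df[[1]])
    taxonomy <- NULL
    if (is.null(taxonomy_path)) {
      cand <- paste0(path, ".taxonomy.tsv")
      if (file.exists(cand)) taxonomy_path <- cand
    }
    if (!is.null(taxonomy_path)) {
      tx <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
      taxonomy <- stats::setNames(as.character(tx[[2]]),
                                  as.character(tx[[1]]))
    }
    otu_table(counts, taxonomy = taxonomy)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for biom-json input")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    otu_table(t(m))
  }
}

#' Write an OTU table to disk
#'
#' Inverse of [read_otu_table()]; the tsv dialect writes the taxonomy (when
#' present) to `<path>.taxonomy.tsv`.
#'
#' @inheritParams read_otu_table
#' @param table an [otu_table].
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom-json")) {
  stopifnot_otu_table(table)
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(table$counts),
                     table$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(table$taxonomy)) {
      tx <- data.frame(otu_id = names(table$taxonomy),
                       taxonomy = unname(table$taxonomy))
      utils::write.table(tx, paste0(path, ".taxonomy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for biom-json output")
    b <- biomformat::make_biom(t(table$counts))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-separated file with required columns `sample_id`, `group`,
#' `longitude`, `latitude`, `altitude`, `temperature`, `precipitation`
#' (column order free). `group` is the categorical label used by the MRPP,
#' RDA and LEfSe stages (province codes in the motivating study); the five
#' covariates are decimal degrees, meters, mean-annual degrees C and annual
#' mm.
#'
#' @param path file path.
#' @return a data.frame with one row per sample, `group` as character.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_sample_metadata
#' @param metadata a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "group", "longitude", "latitude", "altitude",
                "temperature", "precipitation")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  covs <- c("longitude", "latitude", "altitude", "temperature",
            "precipitation")
  for (v in covs) {
    val <- suppressWarnings(as.numeric(metadata[[v]]))
    if (any(is.na(val) | !is.finite(val)))
      stop("non-numeric or non-finite value in metadata column '", v, "'")
    metadata[[v]] <- val
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  if (any(!nzchar(metadata$group)))
    stop("empty group label in metadata")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  metadata
}

#' Join report between a table and its metadata
#'
#' Lists samples present in only one of the two inputs; used by the
#' validation driver so mismatches are flagged rather than silently dropped.
#'
#' @param table an [otu_table].
#' @param metadata a metadata data.frame (see [read_sample_metadata()]).
#' @return list with `matched`, `table_only`, `metadata_only` id vectors.
#' @export
join_report <- function(table, metadata) {
  stopifnot_otu_table(table)
  ids <- sample_ids(table)
  list(matched = intersect(ids, metadata$sample_id),
       table_only = setdiff(ids, metadata$sample_id),
       metadata_only = setdiff(metadata$sample_id, ids))
}

#' Read a rooted phylogenetic tree in Newick format
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this pipeline
#' needs: unique tip labels and non-negative branch lengths. Use
#' [tree_tip_report()] to reconcile tips with a table's OTU ids.
#'
#' @param path Newick file path.
#' @return an [ape] `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in file")
  validate_tree(tree)
}

#' @rdname read_phylo_tree
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a phylo tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in tree")
  tree
}

#' @rdname read_phylo_tree
#' @param table an [otu_table] whose OTU ids are compared with the tips.
#' @return for `tree_tip_report`: list with `shared`, `missing_from_tree`,
#'   `extra_in_tree`.
#' @export
tree_tip_report <- function(tree, table) {
  stopifnot_otu_table(table)
  list(shared = intersect(otu_ids(table), tree$tip.label),
       missing_from_tree = setdiff(otu_ids(table), tree$tip.label),
       extra_in_tree = setdiff(tree$tip.label, otu_ids(table)))
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample row is divided by its row sum; rows of the result sum to 1
#' within 1e-9. Relative abundance is the currency of the core-selection,
#' RDA and LEfSe stages.
#'
#' @param table an [otu_table] (or a bare counts matrix).
#' @return numeric matrix with the table's dimnames, rows summing to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else
    as.matrix(table)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(counts)[rs == 0], collapse = ", "))
  sweep(counts, 1, rs, "/")
}

#' Subset samples or OTUs of a table
#'
#' `filter_samples` keeps samples by id or by predicate on the ids;
#' `filter_otus` keeps OTUs by id/predicate and/or by minimum total count
#' (e.g. `min_total = 1` drops all-zero OTU columns, which are retained on
#' read by design). Taxonomy is subset accordingly. An empty result is an
#' error, not a silent empty table.
#'
#' @param table an [otu_table].
#' @param keep character vector of ids, logical vector, or predicate
#'   function over ids.
#' @param min_total minimum summed count for an OTU to be kept.
#' @return a validated [otu_table].
#' @export
filter_samples <- function(table, keep) {
  stopifnot_otu_table(table)
  idx <- resolve_keep(keep, sample_ids(table))
  if (!length(idx)) stop("sample filter matched nothing: empty table")
  otu_table(table$counts[idx, , drop = FALSE], taxonomy = table$taxonomy)
}

#' @rdname filter_samples
#' @export
filter_otus <- function(table, keep = NULL, min_total = 0) {
  stopifnot_otu_table(table)
  ids <- otu_ids(table)
  sel <- rep(TRUE, length(ids))
  if (!is.null(keep)) sel <- sel & seq_along(ids) %in% resolve_keep(keep, ids)
  sel <- sel & colSums(table$counts) >= min_total
  if (!any(sel)) stop("OTU filter matched nothing: empty table")
  tx <- table$taxonomy
  if (!is.null(tx)) tx <- tx[names(tx) %in% ids[sel]]
  if (!is.null(tx) && !length(tx)) tx <- NULL
  otu_table(table$counts[, sel, drop = FALSE], taxonomy = tx,
            require_positive_samples = FALSE)
}

resolve_keep <- function(keep, ids) {
  if (is.function(keep)) which(vapply(ids, keep, logical(1)))
  else if (is.logical(keep)) which(rep_len(keep, length(ids)))
  else which(ids %in% keep)
}
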