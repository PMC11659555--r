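#' Construct an omics abundance matrix
#'
#' An `OmicsMatrix` holds a features x samples table of log2 abundances with
#' an explicit observed/missing mask. Missing cells are stored as `NA` and
#' carry no numeric meaning: every statistic in this package is computed over
#' observed cells only. Metabolomics layers must be complete (no missing
#' values), mirroring targeted metabolite panels.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   `NA` at unobserved cells. Must have unique, non-empty dimnames.
#' @param layer Either `"proteomics"` or `"metabolomics"`.
#' @return An object of class `OmicsMatrix`: a list with elements `values`
#'   (numeric matrix with `NA` for missing), `mask` (logical matrix, `TRUE`
#'   where observed) and `layer`.
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("P1", "P2"), c("S1", "S2", "S3"))), "proteomics")
#' feature_ids(m)
#' @export
omics_matrix <- function(values, layer = c("proteomics", "metabolomics")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature rownames and sample colnames")
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) {
    stop("duplicated feature IDs: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicated sample IDs: ", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-finite observed values (Inf/NaN) are not allowed")
  }
  mask <- !is.na(values)
  if (layer == "metabolomics" && !all(mask)) {
    stop("metabolomics layers must be complete: ",
         sum(!mask), " missing cells found")
  }
  structure(list(values = values, mask = mask, layer = layer),
            class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix (%s): %d features x %d samples, %.1f%% missing\n",
              x$layer, nrow(x$values), ncol(x$values),
              100 * mean(!x$mask)))
  invisible(x)
}

#' @rdname omics_matrix
#' @param m An `OmicsMatrix`.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

stopifnot_omics <- function(m) {
  if (!inherits(m, "OmicsMatrix")) stop("expected an OmicsMatrix")
  invisible(m)
}

#' Read an abundance matrix from a tab-separated file
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' Empty cells and the token `"NA"` both denote missing values. Any other
#' non-numeric cell is an error.
#'
#' @param path Path to a TSV file.
#' @param layer Either `"proteomics"` or `"metabolomics"`.
#' @return An [omics_matrix()].
#' @seealso [write_matrix()] for the inverse; the pair round-trips exactly
#'   for finite values.
#' @export
read_matrix <- function(path, layer = c("proteomics", "metabolomics")) {
  layer <- match.arg(layer)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(tab) < 2) stop("matrix file needs a feature column plus >=1 sample")
  fids <- tab[[1L]]
  sids <- colnames(tab)[-1L]
  dup_s <- unique(sids[duplicated(sids)])
  if (length(dup_s)) {
    stop("duplicated sample IDs in ", path, ": ", paste(dup_s, collapse = ", "))
  }
  dup_f <- unique(fids[duplicated(fids)])
  if (length(dup_f)) {
    stop("duplicated feature IDs in ", path, ": ", paste(dup_f, collapse = ", "))
  }
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  missing <- cells == "" | cells == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !missing & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 cells[bad][1L], fids[i[1L]], sids[i[2L]]))
  }
  num[missing] <- NA_real_
  dimnames(num) <- list(fids, sids)
  omics_matrix(num, layer)
}

#' Write an abundance matrix to a tab-separated file
#'
#' Missing cells are written as `"NA"`. Numbers are written with full
#' precision (`digits = 17`) so that `read_matrix(write_matrix(m))`
#' reproduces `m` bit-exactly.
#'
#' @param m An `OmicsMatrix`.
#' @param path Output file path.
#' @param id_column Name for the feature-ID column header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  stopifnot_omics(m)
  txt <- format(m$values, digits = 17, trim = TRUE, scientific = FALSE)
  txt[!m$mask] <- "NA"
  out <- cbind(feature = rownames(m$values), txt)
  colnames(out)[1L] <- id_column
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge two measurement batches of the same omics layer
#'
#' Column-binds the samples of both batches. For proteomics the merged
#' feature set is the union of the two batches' features: cells for features
#' absent from a batch are missing in that batch's samples. For metabolomics
#' only features measured in both batches are kept (intersection), so the
#' merged layer stays complete.
#'
#' @param a,b `OmicsMatrix` objects with the same `layer` and disjoint
#'   sample IDs (apply batch suffixes upstream, see [suffix_samples()]).
#' @return Merged `OmicsMatrix`. Feature order: `a`'s features first, then
#'   `b`-only features (union) or `a`'s order restricted to shared features
#'   (intersection).
#' @export
merge_batches <- function(a, b) {
  stopifnot_omics(a); stopifnot_omics(b)
  if (a$layer != b$layer) stop("cannot merge different layers")
  shared <- intersect(sample_ids(a), sample_ids(b))
  if (length(shared)) {
    stop("sample IDs present in both batches: ",
         paste(head(shared, 5L), collapse = ", "))
  }
  if (a$layer == "proteomics") {
    feats <- union(feature_ids(a), feature_ids(b))
  } else {
    feats <- intersect(feature_ids(a), feature_ids(b))
    if (!length(feats)) stop("no metabolite measured in both batches")
  }
  n_a <- ncol(a$values); n_b <- ncol(b$values)
  vals <- matrix(NA_real_, length(feats), n_a + n_b,
                 dimnames = list(feats, c(sample_ids(a), sample_ids(b))))
  vals[intersect(feats, feature_ids(a)), seq_len(n_a)] <-
    a$values[intersect(feats, feature_ids(a)), , drop = FALSE]
  vals[intersect(feats, feature_ids(b)), n_a + seq_len(n_b)] <-
    b$values[intersect(feats, feature_ids(b)), , drop = FALSE]
  omics_matrix(vals, a$layer)
}

#' Suffix sample IDs with their batch label
#'
#' Repeated patient profiles measured in both batches must coexist as
#' distinct columns after merging; suffixing guarantees unique sample IDs
#' while subject identity is kept in the metadata.
#'
#' @param m An `OmicsMatrix`.
#' @param batch Batch label, e.g. `"2018"`.
#' @return The matrix with sample IDs renamed to `<id>_<batch>`.
#' @export
suffix_samples <- function(m, batch) {
  stopifnot_omics(m)
  colnames(m$values) <- paste0(colnames(m$values), "_", batch)
  colnames(m$mask) <- colnames(m$values)
  m
}

#' Subset an OmicsMatrix by features and/or samples
#'
#' @param m An `OmicsMatrix`.
#' @param features,samples Character vectors of IDs (or logical/integer
#'   indices); `NULL` keeps everything.
#' @return The subset `OmicsMatrix`.
#' @export
subset_omics <- function(m, features = NULL, samples = NULL) {
  stopifnot_omics(m)
  v <- m$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, m$layer)
}
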