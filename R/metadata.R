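#' Validate a sample-metadata table
#'
#' Metadata rows describe one sample each: the heart it came from
#' (`subject_id`), the disease condition (`Donor`, `DCM` or `ICM`), the
#' ventricle (`LV`/`RV`), `sex` (`M`/`F`), `age` in years and the
#' measurement `batch` (`2018`/`2020`). A (subject, location, batch) triple
#' identifies at most one sample; samples from the same ventricle of the
#' same heart measured in both batches are technical replicates for
#' normalisation.
#'
#' @param meta A data.frame with columns `sample_id`, `subject_id`,
#'   `condition`, `location`, `sex`, `age`, `batch`.
#' @param m Optional `OmicsMatrix`; if given, every sample of `m` must have
#'   exactly one metadata row, and `meta` is reordered to match.
#' @return The validated (and possibly reordered) data.frame.
#' @export
validate_sample_meta <- function(meta, m = NULL) {
  req <- c("sample_id", "subject_id", "condition", "location", "sex",
           "age", "batch")
  miss <- setdiff(req, colnames(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in setdiff(req, "age")) meta[[col]] <- as.character(meta[[col]])
  meta$age <- as.numeric(meta$age)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad_cond <- setdiff(unique(meta$condition), c("Donor", "DCM", "ICM"))
  if (length(bad_cond)) stop("unknown condition: ", paste(bad_cond, collapse = ", "))
  bad_loc <- setdiff(unique(meta$location), c("LV", "RV"))
  if (length(bad_loc)) stop("unknown location: ", paste(bad_loc, collapse = ", "))
  bad_sex <- setdiff(unique(meta$sex), c("M", "F"))
  if (length(bad_sex)) stop("unknown sex: ", paste(bad_sex, collapse = ", "))
  if (any(!is.finite(meta$age)) || any(meta$age <= 0)) {
    stop("ages must be positive numbers")
  }
  key <- paste(meta$subject_id, meta$location, meta$batch, sep = "|")
  if (anyDuplicated(key)) {
    stop("more than one sample for (subject, location, batch): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (!is.null(m)) {
    stopifnot_omics(m)
    absent <- setdiff(sample_ids(m), meta$sample_id)
    if (length(absent)) {
      stop("samples without metadata: ", paste(head(absent, 5L), collapse = ", "))
    }
    meta <- meta[match(sample_ids(m), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Read / write sample metadata CSV
#'
#' @param path CSV path with the required headers (see
#'   [validate_sample_meta()]).
#' @return `read_sample_meta`: the validated data.frame.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_meta
#' @param meta Validated metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the technical-replicate map used by RUV-III
#'
#' Samples from the same ventricle of the same subject (across batches) form
#' one replicate group. Groups of size one are allowed; the incidence matrix
#' M has one row per sample, one column per group, exactly one 1 per row,
#' and full column rank by construction.
#'
#' @param meta Validated metadata (see [validate_sample_meta()]).
#' @return An object of class `ReplicateMap`: list with `groups` (named list
#'   of sample-ID vectors) and `incidence` (samples x groups 0/1 matrix,
#'   rows in `meta` order).
#' @export
build_replicate_map <- function(meta) {
  meta <- validate_sample_meta(meta)
  key <- paste(meta$subject_id, meta$location, sep = "-")
  groups <- split(meta$sample_id, factor(key, levels = unique(key)))
  M <- matrix(0L, nrow(meta), length(groups),
              dimnames = list(meta$sample_id, names(groups)))
  M[cbind(seq_len(nrow(meta)), match(key, names(groups)))] <- 1L
  structure(list(groups = groups, incidence = M), class = "ReplicateMap")
}

#' @export
print.ReplicateMap <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("ReplicateMap: %d samples in %d groups (%d with replicates)\n",
              nrow(x$incidence), length(x$groups), sum(sizes > 1L)))
  invisible(x)
}
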