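#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are removed; empty member lists are dropped with a warning.
#'
#' @param path GMT file path.
#' @param source Collection flavour, `"KEGG-like"` or `"GO-MF-like"`; purely
#'   descriptive.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors), `descriptions` and `source`.
#' @examples
#' gmt <- read_gmt(system.file("extdata", "example_pathways_synthetic.gmt",
#'                             package = "bivomics"))
#' names(gmt$sets)
#' @export
read_gmt <- function(path, source = c("KEGG-like", "GO-MF-like")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) {
    warning(sum(short), " GMT line(s) without members dropped")
    parts <- parts[!short]
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  geneset_collection(sets,
                     descriptions = setNames(vapply(parts, `[[`, "", 2L), nm),
                     source = source)
}

#' @rdname read_gmt
#' @param sets Named list of character member vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @export
geneset_collection <- function(sets, descriptions = NULL,
                               source = c("KEGG-like", "GO-MF-like")) {
  source <- match.arg(source)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all sets must be named")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("empty member lists are not allowed")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, source = source),
            class = "GeneSetCollection")
}

#' @rdname read_gmt
#' @param gsc A `GeneSetCollection`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection (%s): %d sets, median size %d\n",
              x$source, length(x$sets), as.integer(median(lengths(x$sets)))))
  invisible(x)
}
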