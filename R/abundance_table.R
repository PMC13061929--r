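#' Construct an abundance table
#'
#' The universal currency of the pipeline: a samples x taxa matrix of
#' non-negative genus abundances, either raw read counts or relative
#' abundances (compositions closed to 1).
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from `rownames(values)` when `NULL`.
#' @param taxon_names character vector of unique taxon (genus) names; taken
#'   from `colnames(values)` when `NULL`.
#' @param kind `"counts"` or `"relative"`. Relative tables must have every
#'   row summing to 1 within `1e-9`.
#' @return An object of class `abundance_table` with elements `values`
#'   (named matrix), `sample_ids`, `taxon_names` and `kind`.
#' @export
abundance_table <- function(values, sample_ids = NULL, taxon_names = NULL,
                            kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(taxon_names)) taxon_names <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(taxon_names)) taxon_names <- paste0("taxon", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  taxon_names <- as.character(taxon_names)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (length(taxon_names) != ncol(values))
    stop("taxon_names length does not match column count")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_names))
    stop("duplicate taxon names: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "))
  if (anyNA(values)) stop("abundance values contain NA")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 sample_ids[idx[1]], taxon_names[idx[2]]))
  }
  if (kind == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop("relative table rows must sum to 1: offending sample(s) ",
           paste(utils::head(sample_ids[bad], 5), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, taxon_names)
  structure(list(values = values, sample_ids = sample_ids,
                 taxon_names = taxon_names, kind = kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Number of samples / taxa in an abundance table
#' @param table an `abundance_table`.
#' @return integer count.
#' @export
n_samples <- function(table) nrow(table$values)

#' @rdname n_samples
#' @export
n_taxa <- function(table) ncol(table$values)

stopifnot_abundance <- function(table) {
  if (!inherits(table, "abundance_table"))
    stop("expected an abundance_table")
  invisible(table)
}
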