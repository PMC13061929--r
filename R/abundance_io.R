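#' Read an abundance table from delimited text or BIOM
#'
#' Reads a samples x taxa (or taxa x samples, see `orientation`) table from
#' tab- or comma-delimited text with a header row and row names in the first
#' column, or from a BIOM-format file (`.biom`, requires the biomformat
#' package). The table kind is inferred: when every row sums to 1 (within
#' `1e-6`) the table is treated as relative abundances and re-closed exactly;
#' otherwise it is treated as counts.
#'
#' @param path file path.
#' @param orientation `"samples"` when samples are rows (default) or
#'   `"taxa"` when taxa are rows (the file is transposed on read).
#' @param sep field separator; `NULL` (default) sniffs tab first, then comma.
#' @return an [abundance_table].
#' @export
read_abundance <- function(path, orientation = c("samples", "taxa"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples in BIOM
    m <- t(m)
  } else {
    if (is.null(sep)) {
      first <- readLines(path, n = 1L)
      sep <- if (grepl("\t", first)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    notnum <- !vapply(df, is.numeric, logical(1))
    if (any(notnum)) {
      j <- which(notnum)[1]
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s'%s",
                   colnames(df)[j],
                   if (!is.na(bad)) sprintf(", row '%s'", rownames(df)[bad]) else ""))
    }
    m <- as.matrix(df)
    if (orientation == "taxa") m <- t(m)
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  rs <- rowSums(m)
  if (all(rs > 0) && all(abs(rs - 1) <= 1e-6)) {
    m <- m / rs  # re-close to machine precision
    abundance_table(m, kind = "relative")
  } else {
    abundance_table(m, kind = "counts")
  }
}

#' Write an abundance table to delimited text
#'
#' Mirrors [read_abundance]: samples as rows, header with taxon names, the
#' sample id in the first column.
#'
#' @param table an [abundance_table].
#' @param path output path.
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, sep = "\t") {
  stopifnot_abundance(table)
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Each row is divided by its total so compositions sum to 1, the scale on
#' which all downstream distance, correlation and classification steps
#' operate.
#'
#' @param table an [abundance_table] with `kind = "counts"`.
#' @return an [abundance_table] with `kind = "relative"`.
#' @export
to_relative <- function(table) {
  stopifnot_abundance(table)
  if (table$kind != "counts")
    stop("to_relative expects a counts table; input is already relative")
  rs <- rowSums(table$values)
  if (any(rs <= 0))
    stop("zero-sum row(s): ",
         paste(table$sample_ids[rs <= 0], collapse = ", "))
  abundance_table(table$values / rs, table$sample_ids, table$taxon_names,
                  kind = "relative")
}

#' Pool rarely detected taxa into a single category
#'
#' A taxon's detection rate is the fraction of samples in which it has a
#' value greater than zero (at least one read, for counts). Taxa with
#' detection rate less than or equal to `threshold` are summed column-wise
#' into a single pooled category; taxa strictly above the threshold are kept
#' unchanged. A pre-existing `"Unclassified"` column is always kept as its
#' own variable, regardless of its detection rate. Output column order is
#' kept taxa in input order, then `"Unclassified"` (when present), then the
#' pooled category — stable so downstream model coefficients are
#' reproducible.
#'
#' @param table an [abundance_table] (counts or relative).
#' @param threshold detection-rate cutoff in `[0, 1]`; taxa with detection
#'   rate `<= threshold` are pooled (default 0.5).
#' @param pooled_name name of the pooled category (default `"Other genera"`).
#' @param unclassified_name name of the column exempt from pooling.
#' @return a list with elements `table` (the filtered [abundance_table]) and
#'   `report` (a `filter_report`: per-taxon detection rate, kept and pooled
#'   taxon names, pooled category name).
#' @export
filter_by_detection_rate <- function(table, threshold = 0.5,
                                     pooled_name = "Other genera",
                                     unclassified_name = "Unclassified") {
  stopifnot_abundance(table)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  v <- table$values
  detection <- colMeans(v > 0)
  names(detection) <- table$taxon_names
  is_uncl <- table$taxon_names == unclassified_name
  pooled <- detection <= threshold & !is_uncl
  kept <- !pooled
  kept_names <- table$taxon_names[kept & !is_uncl]
  if (pooled_name %in% table$taxon_names[kept])
    stop(sprintf("pooled category name '%s' collides with a kept taxon",
                 pooled_name))
  ord <- c(kept_names, table$taxon_names[is_uncl])
  out <- v[, ord, drop = FALSE]
  if (any(pooled)) {
    other <- rowSums(v[, pooled, drop = FALSE])
    out <- cbind(out, other)
    colnames(out) <- c(ord, pooled_name)
  }
  report <- structure(
    list(detection_rate = detection,
         kept = table$taxon_names[kept],
         pooled = table$taxon_names[pooled],
         pooled_name = pooled_name,
         threshold = threshold),
    class = "filter_report")
  list(table = abundance_table(out, table$sample_ids, colnames(out),
                               kind = table$kind),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d taxa kept, %d pooled into '%s' (detection rate <= %g)\n",
              length(x$kept), length(x$pooled), x$pooled_name, x$threshold))
  invisible(x)
}
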