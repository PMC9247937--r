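#' Construct a property table
#'
#' A property table holds P amino-acid indices as a P x 20 numeric
#' matrix whose columns follow the canonical order \code{\link{AA_ORDER}}.
#' Missing entries are tracked in a logical mask so that imputation
#' stays auditable.
#'
#' @param values numeric P x 20 matrix; \code{NA} entries are allowed
#'   and flagged missing.
#' @param index_ids character vector of P unique accession strings.
#' @param source free-text provenance string.
#' @return An object of class \code{property_table} with elements
#'   \code{index_ids}, \code{values} (NAs kept), \code{missing_mask}
#'   and \code{source}.
#' @export
property_table <- function(values, index_ids, source = "unknown") {
  values <- as.matrix(values)
  if (ncol(values) != 20L) {
    stop("property table must have exactly 20 amino-acid columns, got ",
         ncol(values))
  }
  if (nrow(values) < 2L) {
    stop("property table needs at least 2 index rows")
  }
  index_ids <- as.character(index_ids)
  if (length(index_ids) != nrow(values)) {
    stop("index_ids length does not match row count")
  }
  if (anyDuplicated(index_ids)) {
    stop("duplicate index accessions: ",
         paste(unique(index_ids[duplicated(index_ids)]), collapse = ", "))
  }
  storage.mode(values) <- "double"
  n_ok <- rowSums(!is.na(values))
  if (any(n_ok < 2L)) {
    stop("index rows with fewer than 2 observed values: ",
         paste(index_ids[n_ok < 2L], collapse = ", "))
  }
  dimnames(values) <- list(index_ids, AA_ORDER)
  structure(
    list(index_ids = index_ids,
         values = values,
         missing_mask = is.na(values),
         source = source),
    class = "property_table"
  )
}

#' @export
print.property_table <- function(x, ...) {
  cat("property_table:", nrow(x$values), "indices x 20 amino acids\n")
  cat("  missing entries:", sum(x$missing_mask),
      " source:", x$source, "\n")
  invisible(x)
}

#' Parse an AAindex1 flat file
#'
#' Reads the AAindex1 text format: records begin with an \code{H}
#' accession line, the numeric block is introduced by an \code{I} line
#' followed by two rows of ten values (amino-acid order
#' A R N D C Q E G H I / L K M F P S T W Y V, i.e. already the
#' canonical order), and records end with \code{//}.  \code{NA} tokens
#' are recorded in the missing mask.
#'
#' @param path path to an AAindex1-format file.
#' @param source provenance string stored on the table; defaults to the
#'   file name.
#' @return A \code{\link{property_table}}.
#' @export
read_aaindex <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("empty AAindex file: ", path)
  }
  ids <- character(0)
  rows <- list()
  acc <- NA_character_
  in_numeric <- FALSE
  tokens <- character(0)

  flush_record <- function() {
    if (is.na(acc)) return(invisible(NULL))
    if (length(tokens) != 20L) {
      stop("malformed AAindex record ", acc, ": expected 20 values, got ",
           length(tokens))
    }
    vals <- suppressWarnings(as.numeric(tokens))
    vals[toupper(tokens) %in% c("NA", "NA.")] <- NA_real_
    if (any(is.na(vals) & !toupper(tokens) %in% c("NA", "NA."))) {
      stop("malformed AAindex record ", acc, ": non-numeric token")
    }
    ids[[length(ids) + 1L]] <<- acc
    rows[[length(rows) + 1L]] <<- vals
    invisible(NULL)
  }

  for (ln in lines) {
    tag <- substr(ln, 1L, 1L)
    if (tag == "H") {
      acc <- trimws(substr(ln, 2L, nchar(ln)))
      in_numeric <- FALSE
      tokens <- character(0)
    } else if (tag == "I") {
      in_numeric <- TRUE
    } else if (startsWith(ln, "//")) {
      flush_record()
      acc <- NA_character_
      in_numeric <- FALSE
      tokens <- character(0)
    } else if (in_numeric) {
      tokens <- c(tokens, strsplit(trimws(ln), "\\s+")[[1]])
    }
  }
  if (!is.na(acc)) flush_record()  # tolerate a missing trailing //
  if (length(rows) == 0L) stop("no AAindex records found in ", path)
  property_table(do.call(rbind, rows), ids, source = source)
}

#' Load the AAindex snapshot bundled with seqinr
#'
#' Convenience constructor turning \code{seqinr}'s packaged AAindex
#' release (544 indices) into a \code{\link{property_table}}.  Useful
#' when the current AAindex1 flat file has not been downloaded.
#'
#' @return A \code{\link{property_table}} with one row per packaged index.
#' @export
aaindex_snapshot <- function() {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("the seqinr package is required for aaindex_snapshot()")
  }
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aa <- env$aaindex
  vals <- t(vapply(aa, function(x) unname(x$I), numeric(20)))
  property_table(vals, names(aa), source = "seqinr aaindex snapshot")
}

#' Impute missing property values with row means
#'
#' Replaces each missing cell by the mean of that index's observed
#' values, keeping every index row so that all of them enter the
#' clustering step.  The missing mask is retained for provenance.
#'
#' @param table a \code{\link{property_table}}.
#' @return The table with \code{values} free of \code{NA}.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "property_table"))
  v <- table$values
  if (!anyNA(v)) return(table)
  rmeans <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- rmeans[idx[, 1L]]
  table$values <- v
  table
}
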