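#' Read protein sequences from a FASTA file
#'
#' IDs are the first whitespace-delimited token of each header,
#' sequences are uppercased and wrapped lines joined; record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(raw[[1]], ">")) {
    stop("FASTA parse error: sequence data before the first header")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("header without sequence: ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output path.
#' @param width line-wrap width; default 60.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a dissimilarity matrix in PHYLIP square format
#'
#' First line is the sequence count; each following line is an ID and
#' its full row.  Values are printed with 6 significant digits for
#' interoperability; use the CSV writer for full precision.
#'
#' @param m symmetric dissimilarity matrix with IDs as dimnames.
#' @param path output path.
#' @param strict_names truncate IDs to 10 characters (classic PHYLIP);
#'   default \code{FALSE} keeps full whitespace-free IDs.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(m, path, strict_names = FALSE) {
  m <- check_dissimilarity_matrix(m)
  ids <- rownames(m)
  if (strict_names) ids <- substr(ids, 1L, 10L)
  if (any(grepl("\\s", ids))) stop("PHYLIP IDs must not contain whitespace")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(ids[i], sprintf("%.6g", m[i, ])), collapse = "  "),
               con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path path to a PHYLIP square matrix file.
#' @return Symmetric numeric matrix with IDs as dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[[1]]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop("malformed PHYLIP matrix: expected ", n, " rows")
  }
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    if (length(tok) != n + 1L) {
      stop("malformed PHYLIP row ", i, ": expected ", n, " values")
    }
    ids[i] <- tok[[1]]
    m[i, ] <- as.numeric(tok[-1])
  }
  dimnames(m) <- list(ids, ids)
  check_dissimilarity_matrix(m)
}

#' Write a dissimilarity matrix as CSV (full precision)
#'
#' @param m symmetric dissimilarity matrix with IDs as dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  m <- check_dissimilarity_matrix(m)
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissimilarity matrix from CSV
#'
#' @param path CSV written by \code{\link{write_matrix_csv}} (first
#'   column \code{id}, remaining columns the square matrix).
#' @return Symmetric numeric matrix with IDs as dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  check_dissimilarity_matrix(m)
}

#' Read sequence class labels from a two-column TSV
#'
#' @param path TSV with columns \code{id} and \code{class} (no header
#'   required; a header line "id\\tclass" is tolerated).
#' @return Named character vector mapping ID to class.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "class"),
                          colClasses = "character")
  if (nrow(df) > 0L && identical(tolower(df$id[1]), "id")) df <- df[-1L, ]
  if (anyDuplicated(df$id)) stop("duplicate IDs in label file")
  stats::setNames(df$class, df$id)
}

#' Write sequence class labels as TSV
#'
#' @param labels named vector mapping ID to class.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), class = unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
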