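#' Shift-minimised Euclidean distance between two blocks
#'
#' Given the shifted encodings of block \code{i} of two sequences, the
#' block distance is the minimum Euclidean distance between any pair of
#' shifted variants: all \code{(2d+1)^2} combinations of the shift of
#' one block against the shift of the other are scored.
#'
#' @param enc1,enc2 \code{(2d+1) x 5C} matrices of block encodings,
#'   rows indexed by shift, as stored in a \code{sequence_encoding}.
#' @return The minimal Euclidean distance (nonnegative scalar).
#' @export
block_distance <- function(enc1, enc2) {
  if (!identical(dim(enc1), dim(enc2))) {
    stop("block encodings have mismatched shift sets or vector lengths")
  }
  # squared cross-distances via the Gram expansion
  sq <- outer(rowSums(enc1^2), rowSums(enc2^2), "+") - 2 * tcrossprod(enc1, enc2)
  sqrt(max(0, min(sq)))
}

#' Dissimilarity score between two encoded sequences
#'
#' Sums the shift-minimised block distance over all block indices
#' (only same-index blocks are compared).
#'
#' @param encA,encB \code{sequence_encoding} objects produced under the
#'   same joint padding and parameters.
#' @param normalize_by_blocks divide the raw sum by the number of
#'   blocks; default \code{FALSE} (raw sum).
#' @return Nonnegative scalar dissimilarity.
#' @export
sequence_dissimilarity <- function(encA, encB, normalize_by_blocks = FALSE) {
  stopifnot(inherits(encA, "sequence_encoding"),
            inherits(encB, "sequence_encoding"))
  if (encA$n_blocks != encB$n_blocks) {
    stop("sequences were not padded to the same length (",
         encA$n_blocks, " vs ", encB$n_blocks, " blocks); encode them jointly")
  }
  if (!identical(unclass(encA$params), unclass(encB$params))) {
    stop("sequences were encoded with different blocking parameters")
  }
  d <- sum(vapply(seq_len(encA$n_blocks), function(i) {
    block_distance(encA$blocks[[i]], encB$blocks[[i]])
  }, numeric(1)))
  if (normalize_by_blocks) d / encA$n_blocks else d
}

#' Pairwise dissimilarity matrix of a sequence set
#'
#' Pads all sequences jointly to one common block-aligned length,
#' encodes each sequence once, and fills the symmetric matrix of
#' pairwise dissimilarity scores.
#'
#' @param seqs named character vector of residue strings (IDs as
#'   names), e.g. from \code{\link{read_fasta}}.
#' @param classes a \code{\link{property_classes}} object.
#' @param quad the matching \code{\link{quadruple_partition}}.
#' @param params a \code{\link{blocking_params}} object.
#' @param normalize_by_blocks divide each score by the shared block
#'   count; default \code{FALSE}.
#' @return Symmetric n x n numeric matrix with zero diagonal, dimnames
#'   set to the sequence IDs.
#' @export
pcv_dist <- function(seqs, classes, quad, params = blocking_params(),
                     normalize_by_blocks = FALSE) {
  ids <- names(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  padded <- pad_sequences(seqs, params)
  encs <- lapply(padded, encode_sequence, classes = classes, quad = quad,
                 params = params)
  n <- length(encs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in seq_len(n - 1L)) {
    for (q in seq.int(p + 1L, n)) {
      m[p, q] <- m[q, p] <-
        sequence_dissimilarity(encs[[p]], encs[[q]],
                               normalize_by_blocks = normalize_by_blocks)
    }
  }
  m
}

# Shared validation for dissimilarity matrices.
check_dissimilarity_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("dissimilarity matrix must be square")
  if (anyNA(m) || any(!is.finite(m))) stop("dissimilarity matrix has NaN/Inf entries")
  if (any(m < 0)) stop("dissimilarity matrix has negative entries")
  if (max(abs(m - t(m))) > tol) stop("dissimilarity matrix is asymmetric")
  if (any(abs(diag(m)) > tol)) stop("dissimilarity matrix has nonzero diagonal")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("seq", seq_len(nrow(m)))
  }
  m
}
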