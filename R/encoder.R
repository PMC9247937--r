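#' Blocking parameters
#'
#' Parameters of the splitting step: the block size \code{S}, the
#' maximum window shift \code{d} (each block is observed at the
#' \code{2d + 1} shifts \code{-d..d}), and the normalisation constant
#' of the second positional moment (fixed to \code{S} by default, so
#' the moment is scale-free in block length).
#'
#' @param block_size block length S in residues; default 50.
#' @param max_shift maximum shift d; default 5. Must satisfy
#'   \code{d < S}.
#' @param moment_norm denominator constant N of the second positional
#'   moment; defaults to \code{block_size}.
#' @return An object of class \code{blocking_params}.
#' @export
blocking_params <- function(block_size = 50L, max_shift = 5L,
                            moment_norm = block_size) {
  block_size <- as.integer(block_size)
  max_shift <- as.integer(max_shift)
  if (block_size < 1L) stop("block_size must be positive")
  if (max_shift < 0L) stop("max_shift must be nonnegative")
  if (max_shift >= block_size) stop("max_shift must be smaller than block_size")
  if (moment_norm < 1) stop("moment_norm must be positive")
  structure(list(block_size = block_size, max_shift = max_shift,
                 moment_norm = as.numeric(moment_norm)),
            class = "blocking_params")
}

#' Pad sequences to a common block-aligned length
#'
#' All sequences are right-padded with \code{\link{PAD_SYMBOL}} to the
#' smallest multiple of the block size that is at least the longest
#' input length, so every sequence splits into the same number of
#' complete blocks.  Non-standard residue codes (B, J, O, U, Z, X) are
#' replaced by the pad symbol with a warning.
#'
#' @param seqs named character vector (or list) of residue strings;
#'   names are sequence IDs.
#' @param params a \code{\link{blocking_params}} object.
#' @return A list of \code{padded_sequence} objects, each with
#'   \code{id}, \code{residues} (character vector of length L*),
#'   \code{original_length}.
#' @export
pad_sequences <- function(seqs, params = blocking_params()) {
  seqs <- unlist(as.list(seqs))
  if (length(seqs) == 0L) stop("no sequences to pad")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by ID")
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence: ", paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  if (any(grepl("[[:digit:][:space:]]", seqs))) {
    stop("sequence contains digits or whitespace: ",
         paste(names(seqs)[grepl("[[:digit:][:space:]]", seqs)], collapse = ", "))
  }
  S <- params$block_size
  lens <- nchar(seqs)
  l_star <- as.integer(ceiling(max(lens) / S) * S)
  lapply(seq_along(seqs), function(i) {
    res <- strsplit(toupper(seqs[[i]]), "")[[1]]
    bad <- res %in% NONSTANDARD_CODES
    if (any(bad)) {
      warning("sequence ", names(seqs)[i], ": ", sum(bad),
              " non-standard residue(s) treated as pad")
      res[bad] <- PAD_SYMBOL
    }
    unknown <- !(res %in% c(AA_ORDER, PAD_SYMBOL))
    if (any(unknown)) {
      stop("sequence ", names(seqs)[i], ": unrecognised character(s) ",
           paste(unique(res[unknown]), collapse = ""))
    }
    structure(list(id = names(seqs)[i],
                   residues = c(res, rep(PAD_SYMBOL, l_star - length(res))),
                   original_length = lens[[i]]),
              class = "padded_sequence")
  })
}

#' Enumerate shifted block windows of a padded sequence
#'
#' The padded sequence is conceptually flanked by \code{d} pad symbols
#' on each side so every one of the \code{2d + 1} shifts exists for
#' every block.  Block \code{i} at shift \code{j} covers flanked
#' positions \code{(i-1)S + 1 + j .. iS + j} (1-based in the unflanked
#' coordinate system).
#'
#' @param seq a \code{padded_sequence}.
#' @param params a \code{\link{blocking_params}} object.
#' @return A list with one element per block; each element is a
#'   \code{(2d+1) x S} character matrix whose rows (named by shift
#'   \code{-d..d}) are the shifted windows.
#' @export
split_blocks <- function(seq, params = blocking_params()) {
  stopifnot(inherits(seq, "padded_sequence"))
  S <- params$block_size
  d <- params$max_shift
  res <- seq$residues
  l_star <- length(res)
  if (l_star %% S != 0L) stop("padded length is not a multiple of block_size")
  flanked <- c(rep(PAD_SYMBOL, d), res, rep(PAD_SYMBOL, d))
  n_blocks <- l_star %/% S
  shifts <- seq.int(-d, d)
  lapply(seq_len(n_blocks), function(i) {
    w <- t(vapply(shifts, function(j) {
      start <- (i - 1L) * S + 1L + j + d  # + d: offset into the flank
      flanked[start:(start + S - 1L)]
    }, character(S)))
    rownames(w) <- as.character(shifts)
    w
  })
}

#' Physicochemical sum vector of a window
#'
#' Entry \code{c} is the sum over window positions of the studentized
#' class-mean value of the residue at that position for class \code{c};
#' the pad symbol contributes zero.
#'
#' @param window character vector of residues (length S).
#' @param classes a \code{\link{property_classes}} object.
#' @return Numeric vector of length C.
#' @export
physicochemical_vector <- function(window, classes) {
  idx <- match(window, colnames(classes$means))
  idx <- idx[!is.na(idx)]  # pads and unknowns contribute nothing
  if (length(idx) == 0L) return(numeric(classes$n_classes))
  as.vector(classes$means[, idx, drop = FALSE] %*% rep(1, length(idx)))
}

# Per-class residue -> group lookup (1..4; 0 for letters in no group).
quad_lookup <- function(quad) {
  lapply(quad$groups, function(g) {
    out <- stats::setNames(rep(0L, 26L), LETTERS)
    for (k in 1:4) out[g[[k]]] <- k
    out
  })
}

#' Second positional moment vector of a window
#'
#' For every (class, quadruple group) pair, counts the residues of the
#' window belonging to the group (\eqn{N_S}), their mean 1-based
#' position (\eqn{\mu_S}), and the normalised second positional moment
#' \deqn{D_2^S = \sum_i (i - \mu_S)^2 f_N(S_i) / (N_S N),}
#' where \eqn{f_N} indicates group membership and \eqn{N} is the
#' moment normalisation constant (the block size by default).  Empty
#' groups contribute 0.  The resulting 4C vector (class-major, then
#' group) is studentized across its entries.
#'
#' @param window character vector of residues (length S).
#' @param quad a \code{\link{quadruple_partition}}.
#' @param params a \code{\link{blocking_params}} object.
#' @param moments if \code{TRUE}, attach the raw per-group
#'   \code{N}/\code{mu}/\code{D2} table as attribute \code{"moments"}.
#' @return Numeric vector of length 4C (studentized D2 moments).
#' @export
statistical_vector <- function(window, quad, params = blocking_params(),
                               moments = FALSE) {
  C <- length(quad$groups)
  Nnorm <- params$moment_norm
  lk <- quad_lookup(quad)
  d2 <- numeric(4L * C)
  raw <- if (moments) vector("list", C) else NULL
  for (c_i in seq_len(C)) {
    codes <- lk[[c_i]][window]
    codes[is.na(codes)] <- 0L  # pad / letters outside the alphabet
    for (g in 1:4) {
      pos <- which(codes == g)
      n <- length(pos)
      k <- (c_i - 1L) * 4L + g
      if (n > 0L) {
        mu <- mean(pos)
        d2[k] <- sum((pos - mu)^2) / (n * Nnorm)
      }
      if (moments) {
        raw[[c_i]] <- rbind(raw[[c_i]],
                            data.frame(class = c_i, group = g, N = n,
                                       mu = if (n > 0) mean(pos) else 0,
                                       D2 = d2[k]))
      }
    }
  }
  out <- studentize_vector(d2)
  if (moments) attr(out, "moments") <- do.call(rbind, raw)
  out
}

# Studentize a vector across its entries; zero spread -> zeros.
studentize_vector <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Encode one window as a 5C block vector
#'
#' Concatenation of the C physicochemical sums and the 4C studentized
#' second positional moments (550 components for the 110-class AAindex
#' clustering).
#'
#' @param window character vector of residues (length S).
#' @param classes a \code{\link{property_classes}} object.
#' @param quad the matching \code{\link{quadruple_partition}}.
#' @param params a \code{\link{blocking_params}} object.
#' @return Numeric vector of length 5C.
#' @export
encode_block <- function(window, classes, quad, params = blocking_params()) {
  if (classes$n_classes != length(quad$groups)) {
    stop("class matrix (C = ", classes$n_classes,
         ") and quadruple partition (C = ", length(quad$groups),
         ") disagree")
  }
  c(physicochemical_vector(window, classes),
    statistical_vector(window, quad, params))
}

#' Encode every (block, shift) window of a padded sequence
#'
#' @param seq a \code{padded_sequence}.
#' @param classes a \code{\link{property_classes}} object.
#' @param quad the matching \code{\link{quadruple_partition}}.
#' @param params a \code{\link{blocking_params}} object.
#' @return An object of class \code{sequence_encoding}: list with
#'   \code{id}, \code{n_blocks}, \code{params} and \code{blocks}, a
#'   list of \code{(2d+1) x 5C} matrices (rows named by shift).
#' @export
encode_sequence <- function(seq, classes, quad, params = blocking_params()) {
  windows <- split_blocks(seq, params)
  blocks <- lapply(windows, function(w) {
    enc <- t(apply(w, 1L, encode_block, classes = classes, quad = quad,
                   params = params))
    rownames(enc) <- rownames(w)
    enc
  })
  structure(list(id = seq$id, n_blocks = length(blocks),
                 params = params, blocks = blocks),
            class = "sequence_encoding")
}
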