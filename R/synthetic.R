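#' Synthetic amino-acid property table with planted index groups
#'
#' Draws P index rows as noisy copies of \code{n_groups} latent
#' 20-vectors, so that correlations between rows of the same group
#' exceed those between groups.  Stands in for AAindex1 in tests and
#' examples (and is labelled as such in its provenance string).
#'
#' @param P number of index rows; must be at least \code{n_groups}.
#' @param n_groups number of latent groups.
#' @param within_group_correlation target Pearson correlation between
#'   two rows of the same group, in \eqn{[0, 1)}.  The default 0.98
#'   places the table in the regime where the planted partition is
#'   unambiguous, so correlation-space complete-linkage clustering at
#'   the default cophenetic cut recovers it exactly; lower values blur
#'   the group structure progressively.
#' @param n_missing number of cells flagged missing at random
#'   (never leaving a row with fewer than 2 observed values); default 0.
#' @param seed integer seed; the table is bitwise-reproducible per seed.
#' @return A \code{\link{property_table}} with attribute
#'   \code{"planted_groups"} holding the generating group labels.
#' @export
synthetic_property_table <- function(P, n_groups,
                                     within_group_correlation = 0.98,
                                     n_missing = 0L, seed = NULL) {
  if (P < n_groups || n_groups < 1L) stop("need P >= n_groups >= 1")
  r <- within_group_correlation
  if (!is.numeric(r) || r < 0 || r >= 1) {
    stop("within_group_correlation must lie in [0, 1)")
  }
  with_seed(seed, {
    latent <- matrix(stats::rnorm(n_groups * 20L), n_groups, 20L)
    grp <- rep_len(seq_len(n_groups), P)
    vals <- sqrt(r) * latent[grp, , drop = FALSE] +
      sqrt(1 - r) * matrix(stats::rnorm(P * 20L), P, 20L)
    if (n_missing > 0L) {
      cells <- sample.int(P * 20L, n_missing)
      # keep every row with >= 2 observed values
      bad <- table(factor((cells - 1L) %% P + 1L, levels = seq_len(P)))
      if (any(bad > 18L)) stop("n_missing too large for table dimensions")
      vals[cbind((cells - 1L) %% P + 1L, (cells - 1L) %/% P + 1L)] <- NA_real_
    }
    tab <- property_table(vals, sprintf("SYN%04d", seq_len(P)),
                          source = "synthetic planted-group table")
    attr(tab, "planted_groups") <- grp
    tab
  })
}

#' Simulate a protein sequence family with class structure
#'
#' Emulates benchmark datasets of homologous classes: one random
#' ancestor per class, with each descendant derived by i.i.d.
#' substitutions at a per-site rate and random indels (insertions or
#' deletions of bounded length).  Deterministic per seed.
#'
#' @param n_classes number of families; default 4.
#' @param seqs_per_class descendants per family; default 10.
#' @param ancestor_length ancestor length in residues; default 300.
#' @param substitution_rate per-site substitution probability in
#'   \eqn{[0, 1]}; default 0.1.
#' @param indel_rate per-site probability that an indel event starts at
#'   a position, in \eqn{[0, 1]}; default 0.
#' @param max_indel_length maximum indel length; default 5.
#' @param seed integer seed.
#' @return A list with \code{sequences} (named character vector, IDs
#'   \code{<class>_<k>}), \code{labels} (named vector ID -> class) and
#'   \code{tree} (the generating family cladogram as an
#'   \code{ape::phylo}, classes as clades).
#' @export
synthetic_sequence_family <- function(n_classes = 4L, seqs_per_class = 10L,
                                      ancestor_length = 300L,
                                      substitution_rate = 0.1,
                                      indel_rate = 0,
                                      max_indel_length = 5L,
                                      seed = NULL) {
  stopifnot(n_classes >= 1L, seqs_per_class >= 1L, ancestor_length >= 1L)
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  with_seed(seed, {
    class_names <- LETTERS[seq_len(n_classes)]
    seqs <- character(0)
    labels <- character(0)
    for (cl in class_names) {
      anc <- sample(AA_ORDER, ancestor_length, replace = TRUE)
      for (k in seq_len(seqs_per_class)) {
        id <- paste0(cl, "_", k)
        seqs[[id]] <- paste(mutate_sequence(anc, substitution_rate,
                                            indel_rate, max_indel_length),
                            collapse = "")
        labels[[id]] <- cl
      }
    }
    clades <- vapply(class_names, function(cl) {
      tips <- paste0(cl, "_", seq_len(seqs_per_class), ":1")
      if (seqs_per_class == 1L) tips else
        paste0("(", paste(tips, collapse = ","), "):1")
    }, "")
    tree_txt <- if (n_classes == 1L) paste0(clades, ";") else
      paste0("(", paste(clades, collapse = ","), ");")
    list(sequences = seqs, labels = labels,
         tree = ape::read.tree(text = tree_txt))
  })
}

# Apply i.i.d. substitutions then indel events to a residue vector.
mutate_sequence <- function(res, sub_rate, indel_rate, max_indel_length) {
  n <- length(res)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    if (length(hit)) {
      # draw a replacement different from the current residue
      res[hit] <- vapply(res[hit], function(a) {
        sample(setdiff(AA_ORDER, a), 1L)
      }, "")
    }
  }
  if (indel_rate > 0) {
    n_events <- stats::rbinom(1L, length(res), indel_rate)
    for (e in seq_len(n_events)) {
      pos <- sample.int(length(res), 1L)
      len <- sample.int(max_indel_length, 1L)
      if (stats::runif(1) < 0.5) {  # insertion
        res <- append(res, sample(AA_ORDER, len, replace = TRUE), after = pos)
      } else {                      # deletion
        res <- res[-(pos:min(pos + len - 1L, length(res)))]
      }
    }
    if (length(res) == 0L) res <- sample(AA_ORDER, 1L)
  }
  res
}
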