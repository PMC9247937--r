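#' UPGMA tree from a dissimilarity matrix
#'
#' Agglomerates with arithmetic-mean (average) linkage; node heights
#' are half the merge distance, so the result is rooted and
#' ultrametric.
#'
#' @param m symmetric dissimilarity matrix with IDs as dimnames.
#' @return A rooted ultrametric \code{ape::phylo} tree.
#' @export
upgma_tree <- function(m) {
  m <- check_dissimilarity_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 leaves")
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  phy$edge.length <- pmax(phy$edge.length, 0)
  phy
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Saitou-Nei neighbor joining via the Q-criterion (as implemented in
#' \pkg{ape}); negative estimated branch lengths are clamped to zero
#' with a warning.  The result is unrooted.
#'
#' @param m symmetric dissimilarity matrix with IDs as dimnames.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(m) {
  m <- check_dissimilarity_matrix(m)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 leaves; use upgma_tree()")
  phy <- ape::nj(stats::as.dist(m))
  if (any(phy$edge.length < 0)) {
    warning(sum(phy$edge.length < 0),
            " negative branch length(s) clamped to 0")
    phy$edge.length <- pmax(phy$edge.length, 0)
  }
  phy
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are treated as unrooted and the distance is the plain
#' symmetric-difference count of non-trivial bipartitions (even for
#' pairs of binary trees; no normalisation).
#'
#' @param t1,t2 \code{ape::phylo} trees on the same leaf set.
#' @return Nonnegative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ: only in tree 1 {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
         "}, only in tree 2 {",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ","), "}")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Correlation coefficient between two dissimilarity matrices
#'
#' Pearson correlation over the n(n-1)/2 upper-triangle entries, with
#' the second matrix re-ordered so rows align by sequence ID rather
#' than by position.
#'
#' @param m1,m2 symmetric dissimilarity matrices sharing one ID set.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
matrix_correlation <- function(m1, m2) {
  m1 <- check_dissimilarity_matrix(m1)
  m2 <- check_dissimilarity_matrix(m2)
  if (nrow(m1) < 3L) stop("need at least 3 sequences")
  if (!setequal(rownames(m1), rownames(m2))) {
    stop("matrices do not share an ID set")
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  ut <- upper.tri(m1)
  x <- m1[ut]
  y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant off-diagonal entries make the correlation undefined")
  }
  stats::cor(x, y)
}

#' Pairwise ROC curve and AUC from a dissimilarity matrix
#'
#' Treats every unordered sequence pair as a binary instance (positive
#' when both sequences carry the same class label) scored by the
#' negated dissimilarity, sweeps the score thresholds to trace the ROC
#' curve, and computes the AUC as the tie-corrected Mann-Whitney rank
#' statistic.
#'
#' @param m symmetric dissimilarity matrix with IDs as dimnames.
#' @param labels named vector mapping every sequence ID to a class.
#' @return An object of class \code{pcv_roc}: list with \code{auc},
#'   \code{fpr}, \code{tpr}, \code{thresholds}, \code{n_positive},
#'   \code{n_negative}.
#' @export
pairwise_roc <- function(m, labels) {
  m <- check_dissimilarity_matrix(m)
  ids <- rownames(m)
  if (!all(ids %in% names(labels))) {
    stop("unlabelled sequence IDs: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  }
  lab <- labels[ids]
  ut <- which(upper.tri(m), arr.ind = TRUE)
  positive <- lab[ut[, 1L]] == lab[ut[, 2L]]
  score <- -m[upper.tri(m)]
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: all pairs have the same polarity")
  }
  # Mann-Whitney with midranks handles tied scores exactly
  r <- rank(score)
  auc <- (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # stepwise ROC by threshold sweep (classify positive when score >= t)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(positive & score >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!positive & score >= t) / n_neg, numeric(1))
  structure(list(auc = auc, fpr = fpr, tpr = tpr, thresholds = thr,
                 n_positive = n_pos, n_negative = n_neg),
            class = "pcv_roc")
}

#' @export
print.pcv_roc <- function(x, ...) {
  cat("pairwise ROC:", x$n_positive, "positive /", x$n_negative,
      "negative pairs; AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}
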