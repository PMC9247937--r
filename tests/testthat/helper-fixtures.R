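# Fixtures and independent oracles shared across the suite.

# Wrap a bare C x 20 matrix of class means (already on any scale) as a
# property_classes object, studentizing rows the same way the pipeline
# does.  Used to build toy class matrices of arbitrary C.
make_classes <- function(means) {
  colnames(means) <- AA_ORDER
  rownames(means) <- paste0("C", seq_len(nrow(means)))
  structure(
    list(class_labels = rownames(means),
         means = pcv:::studentize_rows(means),
         raw_means = means,
         member_map = as.list(rownames(means)),
         n_classes = nrow(means)),
    class = "property_classes")
}

random_classes <- function(C, seed) {
  set.seed(seed)
  make_classes(matrix(rnorm(C * 20L), C, 20L))
}

random_window <- function(S, pad_frac = 0) {
  pool <- c(AA_ORDER, rep(PAD_SYMBOL, round(20 * pad_frac)))
  sample(pool, S, replace = TRUE)
}

random_protein <- function(len) {
  paste(sample(AA_ORDER, len, replace = TRUE), collapse = "")
}

# A tiny two-record AAindex1 flat file (synthetic values).
aaindex_fixture <- function(values2 = NULL) {
  v1 <- sprintf("%6.2f", 1:20 / 10)
  v2 <- if (is.null(values2)) sprintf("%6.2f", 20:1 / 10) else values2
  paste(c(
    "H TEST000101",
    "D synthetic index one",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste(v1[1:10], collapse = " "),
    paste(v1[11:20], collapse = " "),
    "//",
    "H TEST000102",
    "D synthetic index two",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste(v2[1:10], collapse = " "),
    paste(v2[11:20], collapse = " "),
    "//"), collapse = "\n")
}

# Independent oracle for the statistical vector: literal per-position
# triple loop over (class, group, position) following the moment
# definitions, with its own studentization.
naive_stat_vector <- function(window, quad, S, Nnorm) {
  C <- length(quad$groups)
  d2 <- numeric(4 * C)
  for (c_i in seq_len(C)) {
    for (g in 1:4) {
      members <- quad$groups[[c_i]][[g]]
      f <- integer(S)
      for (i in seq_len(S)) f[i] <- as.integer(window[i] %in% members)
      n <- sum(f)
      if (n > 0) {
        mu <- 0
        for (i in seq_len(S)) mu <- mu + i * f[i] / n
        acc <- 0
        for (i in seq_len(S)) acc <- acc + (i - mu)^2 * f[i] / (n * Nnorm)
        d2[(c_i - 1) * 4 + g] <- acc
      }
    }
  }
  s <- sd(d2)
  if (!is.finite(s) || s == 0) numeric(4 * C) else (d2 - mean(d2)) / s
}

# Brute-force complete-linkage agglomeration cut at height h: merge the
# closest pair of clusters (farthest-member distance) while that
# distance does not exceed h.
bf_complete_cut <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq.int(a + 1L, length(clusters))) {
        dd <- max(D[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# Canonicalize a flat clustering so partitions can be compared
# irrespective of label numbering.
canonical_partition <- function(labels) {
  f <- factor(labels, levels = unique(labels))
  as.integer(f)
}

# Enumerate the non-trivial bipartitions of a phylo tree (as canonical
# strings) by collecting, for every internal edge, the tip set below it.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  desc_tips <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(edge[edge[, 1] == node, 2], desc_tips))
  }
  splits <- character(0)
  for (k in seq_len(nrow(edge))) {
    child <- edge[k, 2]
    if (child <= n) next
    side <- sort(desc_tips(child))
    if (length(side) < 2L || length(side) > n - 2L) next
    ref <- sort(tree$tip.label)[1]
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

rf_oracle <- function(t1, t2) {
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Area under the stepwise ROC curve by trapezoidal integration — the
# sweep-based oracle for the rank-statistic AUC.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# Ultrametricity check: all root-to-leaf path lengths equal.
is_ultrametric <- function(tree, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(tree)
  leaf_depths <- depths[seq_len(length(tree$tip.label))]
  max(leaf_depths) - min(leaf_depths) < tol
}
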