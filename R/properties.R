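#' Pearson correlation between property indices
#'
#' Correlates every pair of index rows across their 20 amino-acid
#' values, producing the P x P matrix that defines the correlation
#' space in which indices are clustered.
#'
#' @param table an imputed \code{\link{property_table}} (no \code{NA}s).
#' @return Symmetric P x P matrix with unit diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @export
property_correlation <- function(table) {
  stopifnot(inherits(table, "property_table"))
  v <- table$values
  if (anyNA(v)) stop("property table has missing values; run impute_missing() first")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant index rows make correlation undefined: ",
         paste(table$index_ids[sds == 0], collapse = ", "))
  }
  corr <- stats::cor(t(v))
  dimnames(corr) <- list(table$index_ids, table$index_ids)
  corr
}

#' Cluster property indices in correlation space
#'
#' Each index is represented by its row of the correlation matrix;
#' pairwise Euclidean distances between these rows feed complete
#' (farthest-point) linkage, and flat clusters are cut where the
#' cophenetic distance does not exceed
#' \code{threshold_fraction * max(pairwise distance)}.
#'
#' @param corr symmetric P x P correlation matrix with unit diagonal.
#' @param threshold_fraction fraction of the maximum pairwise Euclidean
#'   distance used as the cophenetic cut height; default 0.2.
#' @return Integer vector of cluster labels (1-based, in input order),
#'   named by index accession when \code{corr} has dimnames.
#' @export
cluster_properties <- function(corr, threshold_fraction = 0.2) {
  corr <- as.matrix(corr)
  if (nrow(corr) < 2L) stop("need at least 2 properties to cluster")
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal")
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0) {
    stop("threshold_fraction must be positive")
  }
  d <- stats::dist(corr, method = "euclidean")
  h <- threshold_fraction * max(d)
  hc <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(hc, h = h)
  names(labels) <- rownames(corr)
  labels
}

#' Build the studentized class-mean matrix
#'
#' Averages the member index rows of each cluster per amino acid, then
#' studentizes each class row across the 20 amino acids (subtract the
#' row mean, divide by the row sample standard deviation).  Constant
#' mean rows are set to all zeros with a warning.
#'
#' @param table an imputed \code{\link{property_table}}.
#' @param labels cluster labels as returned by
#'   \code{\link{cluster_properties}}, one per index row.
#' @return An object of class \code{property_classes} with elements
#'   \code{class_labels}, \code{means} (C x 20, studentized),
#'   \code{raw_means} (pre-studentization), \code{member_map} and
#'   \code{n_classes}.
#' @export
class_means <- function(table, labels) {
  stopifnot(inherits(table, "property_table"))
  v <- table$values
  if (anyNA(v)) stop("property table has missing values; run impute_missing() first")
  if (length(labels) != nrow(v)) stop("labels must cover all property rows")
  lab <- as.integer(factor(labels, levels = unique(labels)))
  class_labels <- paste0("C", sort(unique(lab)))
  raw <- rowsum(v, lab) / as.vector(table(lab))
  rownames(raw) <- class_labels
  means <- studentize_rows(raw)
  member_map <- split(table$index_ids, lab)
  names(member_map) <- class_labels
  structure(
    list(class_labels = class_labels,
         means = means,
         raw_means = raw,
         member_map = member_map,
         n_classes = nrow(means)),
    class = "property_classes"
  )
}

# Row-wise studentization: (x - mean) / sample sd; constant rows -> 0
# with a warning (they carry no discriminating signal).
studentize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning("constant class row(s) studentized to zeros: ",
            paste(rownames(m)[const], collapse = ", "))
    s[const] <- 1
  }
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}

#' @export
print.property_classes <- function(x, ...) {
  cat("property_classes:", x$n_classes, "classes x 20 amino acids\n")
  sizes <- lengths(x$member_map)
  cat("  member counts: min", min(sizes), "median", stats::median(sizes),
      "max", max(sizes), "\n")
  invisible(x)
}

#' Quadruple classification of amino acids per property class
#'
#' Splits the value range of each (studentized) class row into four
#' equal-width bins and assigns each amino acid to its bin.  Bins are
#' left-closed/right-open except the last, which is closed; a constant
#' row puts all amino acids in group 1.
#'
#' @param classes a \code{\link{property_classes}} object, or a numeric
#'   matrix with column names (one row per class).
#' @return An object of class \code{quadruple_partition}: a list with
#'   \code{groups} (per class, a list of 4 character vectors
#'   partitioning the alphabet) and \code{bin_edges} (per class, 5
#'   ascending reals).
#' @export
quadruple_partition <- function(classes) {
  m <- if (inherits(classes, "property_classes")) classes$means else as.matrix(classes)
  if (is.null(colnames(m))) colnames(m) <- AA_ORDER[seq_len(ncol(m))]
  groups <- vector("list", nrow(m))
  edges <- vector("list", nrow(m))
  for (c_i in seq_len(nrow(m))) {
    row <- m[c_i, ]
    e <- min(row) + (0:4) * (max(row) - min(row)) / 4
    g <- bin_assign(row, e)
    groups[[c_i]] <- split(colnames(m), factor(g, levels = 1:4))
    edges[[c_i]] <- e
  }
  names(groups) <- rownames(m)
  names(edges) <- rownames(m)
  structure(list(groups = groups, bin_edges = edges),
            class = "quadruple_partition")
}

# Assign values to the four equal-width bins delimited by `edges`
# (length 5): bin k covers [e_k, e_{k+1}) for k < 4 and [e_4, e_5] for
# the last.  Degenerate range (all edges equal) -> everything in bin 1.
bin_assign <- function(x, edges) {
  if (edges[5] <= edges[1]) return(rep(1L, length(x)))
  k <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(k, 1L), 4L)
}

#' @export
print.quadruple_partition <- function(x, ...) {
  cat("quadruple_partition:", length(x$groups), "classes,",
      "4 groups each over", length(unlist(x$groups[[1]])), "letters\n")
  invisible(x)
}

#' Cluster a property table end to end
#'
#' Convenience pipeline: impute missing values, correlate, cluster,
#' average per class, studentize, and derive the quadruple partition.
#'
#' @param table a \code{\link{property_table}} (missing values allowed).
#' @param threshold_fraction cophenetic cut as a fraction of the
#'   maximum pairwise distance; default 0.2.
#' @return A list with \code{classes} (\code{\link{property_classes}}),
#'   \code{quad} (\code{\link{quadruple_partition}}), \code{labels} and
#'   \code{threshold_fraction}.
#' @export
build_property_classes <- function(table, threshold_fraction = 0.2) {
  table <- impute_missing(table)
  corr <- property_correlation(table)
  labels <- cluster_properties(corr, threshold_fraction)
  classes <- class_means(table, labels)
  quad <- quadruple_partition(classes)
  list(classes = classes, quad = quad, labels = labels,
       threshold_fraction = threshold_fraction)
}

#' Write clustered property classes to a directory
#'
#' Persists the class-mean matrix and quadruple partition as TSV plus a
#' JSON sidecar with the member map and parameters, so downstream runs
#' need not re-cluster.
#'
#' @param x result of \code{\link{build_property_classes}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_property_classes <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  means <- data.frame(class = rownames(x$classes$means),
                      x$classes$means, check.names = FALSE)
  utils::write.table(means, file.path(dir, "class_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  quad_df <- do.call(rbind, lapply(names(x$quad$groups), function(cl) {
    g <- x$quad$groups[[cl]]
    data.frame(class = cl, group = 1:4,
               members = vapply(g, paste, "", collapse = ""))
  }))
  utils::write.table(quad_df, file.path(dir, "quadruple.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(member_map = x$classes$member_map,
               threshold_fraction = x$threshold_fraction,
               bin_edges = x$quad$bin_edges)
  jsonlite::write_json(meta, file.path(dir, "classes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read clustered property classes from a directory
#'
#' Reloads the artefacts written by \code{\link{write_property_classes}}.
#'
#' @param dir directory holding \code{class_means.tsv},
#'   \code{quadruple.tsv} and \code{classes.json}.
#' @return A list with \code{classes} and \code{quad}, compatible with
#'   the encoder functions.
#' @export
read_property_classes <- function(dir) {
  means_df <- utils::read.table(file.path(dir, "class_means.tsv"),
                                sep = "\t", header = TRUE,
                                check.names = FALSE)
  means <- as.matrix(means_df[, -1, drop = FALSE])
  rownames(means) <- means_df$class
  meta <- jsonlite::read_json(file.path(dir, "classes.json"),
                              simplifyVector = TRUE)
  quad_df <- utils::read.table(file.path(dir, "quadruple.tsv"),
                               sep = "\t", header = TRUE,
                               colClasses = c("character", "integer",
                                              "character"),
                               na.strings = NULL)
  groups <- lapply(split(quad_df, factor(quad_df$class,
                                         levels = rownames(means))),
                   function(df) {
                     df <- df[order(df$group), ]
                     stats::setNames(lapply(df$members, function(s) {
                       if (nchar(s) == 0) character(0)
                       else strsplit(s, "")[[1]]
                     }), as.character(1:4))
                   })
  edges <- lapply(meta$bin_edges, as.numeric)
  classes <- structure(
    list(class_labels = rownames(means),
         means = means,
         raw_means = NULL,
         member_map = meta$member_map,
         n_classes = nrow(means)),
    class = "property_classes")
  quad <- structure(list(groups = groups[rownames(means)],
                         bin_edges = edges[rownames(means)]),
                    class = "quadruple_partition")
  list(classes = classes, quad = quad,
       threshold_fraction = meta$threshold_fraction)
}
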