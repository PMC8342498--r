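#' Impute missing values in a feature matrix
#'
#' `"feature_min"` (default) replaces missing cells by the minimum
#' observed value of that feature (row); this mirrors treating zeros
#' after the log floor as "at the detection limit". `"row_mean"` uses
#' the feature mean instead. Features with no observed value at all are
#' dropped.
#'
#' @param m features x samples numeric matrix.
#' @param method imputation rule.
#' @return matrix without missing values.
#' @export
impute_matrix <- function(m, method = c("feature_min", "row_mean")) {
  method <- match.arg(method)
  keep <- rowSums(!is.na(m)) > 0L
  m <- m[keep, , drop = FALSE]
  fill <- apply(m, 1L, if (method == "feature_min") min else mean,
                na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- fill[idx[, 1L]]
  m
}

#' Principal component analysis of samples
#'
#' Columns (samples) are the observations; the matrix is column-centered
#' per feature, with no unit-variance scaling by default. Explained
#' variance fractions are returned both as fractions and formatted
#' percentages (2 decimals).
#'
#' @param m features x samples matrix (missing values imputed first; see
#'   [impute_matrix()]).
#' @param n_components number of components to keep.
#' @param scale. unit-variance scale features before PCA.
#' @param impute imputation rule, or `NULL` to require a complete matrix.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components), `explained` (fractions, all components),
#'   `explained_pct` (character, e.g. `"18.86%"`).
#' @export
pca <- function(m, n_components = 2L, scale. = FALSE,
                impute = "feature_min") {
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 features and 2 samples")
  if (!is.null(impute)) m <- impute_matrix(m, impute)
  x <- t(m)                      # samples in rows
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps))
    stop("constant matrix: no variance to decompose")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained = ev,
       explained_pct = sprintf("%.2f%%", 100 * ev))
}

#' Uncentered correlation distance
#'
#' Cluster 3.0 semantics: similarity
#' \eqn{s = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}} with no mean
#' centering; distance \eqn{1 - s \in [0, 2]}.
#'
#' @param x,y numeric vectors of equal length, neither all-zero.
#' @return distance scalar.
#' @export
uncentered_cor_dist <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector in uncentered correlation")
  1 - sum(x * y) / (nx * ny)
}

#' Pairwise uncentered correlation distance matrix
#' @param m matrix; distances between rows.
#' @return symmetric matrix of distances.
#' @export
uncentered_cor_dist_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm vector in uncentered correlation")
  s <- (m %*% t(m)) / outer(nrm, nrm)
  d <- 1 - s
  diag(d) <- 0
  d
}

#' Hierarchical clustering with uncentered correlation, complete linkage
#'
#' Agglomerative clustering over rows or columns of a feature matrix
#' using the uncentered-correlation distance and complete linkage
#' (merge height = maximum pairwise distance between members). Ties in
#' the minimum inter-cluster distance are broken deterministically by
#' the lowest pair of cluster indices in creation order, making output
#' byte-reproducible. Returns a standard `hclust` object, so
#' [stats::cutree()], [ape::as.phylo()] and plotting all work.
#'
#' @param m feature matrix.
#' @param axis cluster `"rows"` or `"cols"`.
#' @param impute imputation rule applied before clustering (or `NULL`).
#' @return object of class `hclust`.
#' @export
hcluster <- function(m, axis = c("rows", "cols"), impute = "feature_min") {
  axis <- match.arg(axis)
  if (!is.null(impute)) m <- impute_matrix(m, impute)
  if (axis == "cols") m <- t(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- uncentered_cor_dist_matrix(m)
  complete_linkage(d, labels)
}

# Complete-linkage agglomeration on a distance matrix with deterministic
# lowest-index-first tie-breaking. Builds the hclust merge/height/order
# representation directly.
complete_linkage <- function(d, labels = NULL) {
  n <- nrow(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)            # indices into d (cluster creation order)
  id <- -seq_len(n)               # hclust coding: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  dd <- d
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      v <- dd[active[i], active[j]]
      if (v < bestd) { bestd <- v; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    a <- id[i]; b <- id[j]
    merge[step, ] <- sort(c(a, b))
    height[step] <- bestd
    # complete linkage: distance of the union to others is the max
    new_members <- c(members[[i]], members[[j]])
    ai <- active[i]
    for (t in seq_len(k)) {
      if (t == i || t == j) next
      at <- active[t]
      dd[ai, at] <- dd[at, ai] <- max(dd[active[i], at], dd[active[j], at])
    }
    members[[i]] <- new_members
    id[i] <- step
    active <- active[-j]; id <- id[-j]; members[j] <- NULL
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge), labels = labels,
             method = "complete", dist.method = "uncentered_correlation",
             call = match.call())
  class(hc) <- "hclust"
  hc
}

# leaf order by in-order traversal of the merge tree (no crossings)
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Export a dendrogram in Newick format
#' @param hc `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
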