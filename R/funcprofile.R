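## funcprofile: functional-category abundance matrices (category x site),
## normalization, PCA across sites, and two-way hierarchical clustering.

#' Column-wise relative abundance
#'
#' Divides each site column of a category x site abundance matrix by its
#' total, so that every site column sums to 1.
#'
#' @param x nonnegative numeric matrix, categories in rows, sites in columns.
#' @return Matrix of per-site relative abundances; attribute `normalization`
#'   set to `"relative"`.
#' @export
relative_abundance <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0)) stop("abundances must be nonnegative")
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0] %||% which(tot == 0)
    stop("zero column total for site(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(m, 2, tot, "/")
  attr(out, "normalization") <- "relative"
  out
}

#' Row standardization across sites
#'
#' Z-scores each category row across sites (mean 0, SD 1), the conventional
#' preparation before two-way clustering so that a few high-abundance
#' categories do not dominate. Constant rows carry no contrast and are
#' dropped with a message.
#'
#' @param x numeric matrix, categories in rows.
#' @return Row-standardized matrix; attribute `dropped_rows` names removed
#'   constant rows, `normalization` set to `"row-standardized"`.
#' @export
standardize_rows <- function(x) {
  m <- as.matrix(x)
  sds <- apply(m, 1, sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    message("dropping ", sum(const), " constant row(s): ",
            paste(head(rownames(m)[const] %||% which(const), 5),
                  collapse = ", "))
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  out <- (m - rowMeans(m)) / sds
  attr(out, "dropped_rows") <- if (any(const))
    rownames(x)[const] %||% which(const) else character(0)
  attr(out, "normalization") <- "row-standardized"
  out
}

#' Agglomerative hierarchical clustering of profile rows
#'
#' Clusters the rows of a matrix (sites or categories) with either Euclidean
#' distance or Pearson correlation distance (`1 - r`), under average or
#' complete linkage. Both recipes used in practice for functional-category
#' profiles are supported; the Euclidean/complete combination is the
#' default.
#'
#' @param x numeric matrix; rows are the items to cluster.
#' @param distance `"euclidean"` or `"pearson"`.
#' @param linkage `"complete"` or `"average"`.
#' @return Object of class `dendrogram_result`: list with the `hclust` tree,
#'   `cophenetic` distances, and the chosen `distance`/`linkage`.
#' @export
hcluster <- function(x, distance = c("euclidean", "pearson"),
                     linkage = c("complete", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as.matrix(x)
  if (any(!is.finite(m))) stop("matrix contains non-finite values")
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  if (distance == "pearson" && ncol(m) < 2)
    stop("pearson distance needs at least 2 variables per item")
  d <- if (distance == "euclidean") dist(m)
       else as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = linkage)
  structure(list(tree = tree, cophenetic = cophenetic(tree),
                 distance = distance, linkage = linkage),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("dendrogram_result: %d items, %s distance, %s linkage\n",
              length(x$tree$order), x$distance, x$linkage))
  invisible(x)
}

#' Cut a dendrogram into k groups
#' @param dend a `dendrogram_result`.
#' @param k number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "dendrogram_result"))
  cutree(dend$tree, k = k)
}

#' Export a dendrogram as Newick
#' @param dend a `dendrogram_result`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "dendrogram_result"))
  ape::write.tree(ape::as.phylo(dend$tree), file = path)
  invisible(path)
}

#' PCA of functional profiles across sites
#'
#' Sites are the observations and categories the variables, i.e. the PCA
#' runs on the transpose of the category x site matrix.
#'
#' @param x category x site matrix (raw, relative, or standardized).
#' @param n_axes number of axes (default 3, capped at the rank).
#' @param scale. correlation-mode PCA? Useful when category scales differ.
#' @return An `ordination_result` with one score row per site.
#' @export
profile_pca <- function(x, n_axes = 3, scale. = FALSE) {
  m <- t(as.matrix(x))
  pca(m, n_axes = min(n_axes, nrow(m) - 1), scale. = scale.)
}
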