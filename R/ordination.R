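## ordination: PCA of feature matrices and PCoA of dissimilarity matrices.

.ordination_result <- function(ids, scores, loadings, eigenvalues,
                               variance_explained, method, notes = NULL) {
  if (ncol(scores) > 0)
    colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  structure(list(ids = ids, scores = scores, loadings = loadings,
                 eigenvalues = eigenvalues,
                 variance_explained = variance_explained,
                 method = method, notes = notes),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  ve <- paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")
  cat(sprintf("%s of %d samples, %d axes (variance explained: %s)\n",
              x$method, length(x$ids), ncol(x$scores), ve))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Principal components analysis
#'
#' PCA of a samples x features matrix via singular value decomposition of the
#' column-centered data (covariance PCA by default; set `scale. = TRUE` for
#' correlation PCA where feature scales differ). Axis signs are fixed
#' deterministically: the largest-magnitude loading on each axis is positive.
#'
#' @param x numeric matrix, samples in rows.
#' @param n_axes number of axes to return (default: full rank). More axes
#'   than the matrix rank are truncated with a message.
#' @param scale. divide centered columns by their SD first?
#' @return An `ordination_result` with `scores`, `loadings`, `eigenvalues`
#'   and per-axis `variance_explained` (fractions of total variance).
#' @export
pca <- function(x, n_axes = NULL, scale. = FALSE) {
  X <- as.matrix(x)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (!all(is.finite(X))) stop("non-finite entries in matrix")
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  Xc <- scale(X, center = TRUE, scale = scale.)
  if (scale.) Xc[, attr(Xc, "scaled:scale") == 0] <- 0
  sv <- svd(Xc)
  ev <- sv$d^2 / (nrow(X) - 1)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  n_axes <- n_axes %||% rank
  notes <- NULL
  if (n_axes > rank) {
    notes <- sprintf("requested %d axes, truncated to rank %d", n_axes, rank)
    message(notes)
    n_axes <- rank
  }
  keep <- seq_len(n_axes)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_axes)
  loadings <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest |loading| positive per axis
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ids
  rownames(loadings) <- colnames(X)
  tot <- sum(ev)
  .ordination_result(ids, scores, loadings, ev[keep],
                     if (tot > 0) ev[keep] / tot else rep(0, n_axes),
                     "PCA", notes)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the squared
#' dissimilarities are double-centered (Gower centering) and
#' eigen-decomposed. Axes with negative eigenvalues (non-Euclidean input,
#' e.g. Gower dissimilarities with missing data) are dropped; their summed
#' magnitude is recorded in `notes` and attribute `negative_variance`.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param n_axes number of axes to return (default: all positive axes).
#' @return An `ordination_result`; `variance_explained` is relative to the
#'   sum of positive eigenvalues.
#' @export
pcoa <- function(d, n_axes = NULL) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(D < 0)) stop("dissimilarities must be nonnegative")
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg_var <- sum(abs(eg$values[eg$values < -tol]))
  ev <- eg$values[pos]
  V <- eg$vectors[, pos, drop = FALSE]
  n_axes <- min(n_axes %||% length(ev), length(ev))
  keep <- seq_len(n_axes)
  scores <- V[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), n_axes)
  for (j in keep) { # deterministic sign: largest |score| positive
    i <- which.max(abs(scores[, j]))
    if (length(i) && scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- ids
  notes <- if (neg_var > 0)
    sprintf("dropped negative eigenvalues (summed magnitude %.3g)", neg_var)
  out <- .ordination_result(ids, scores, NULL, ev[keep],
                            if (sum(ev) > 0) ev[keep] / sum(ev) else
                              rep(0, n_axes),
                            "PCoA", notes)
  attr(out, "negative_variance") <- neg_var
  out
}
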