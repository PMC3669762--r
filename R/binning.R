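## binning: Monte-Carlo consensus k-means over composition vectors.
##
## Each (k, trial) pair is one independently seeded k-means run; the support
## matrix records the fraction of runs in which each scaffold pair shared a
## cluster, pooled over every run. Bins are connected components of the
## support graph thresholded at the configured support level, keeping only
## components of at least min_cluster_size scaffolds.

#' Configuration for consensus clustering
#'
#' @param min_scaffold_length minimum scaffold length in bases
#'   (default 10000, restricting the analysis to dominant assemblies).
#' @param k_values integer vector of k-means cluster counts to pool over.
#'   Default is single-k mode `8`; range mode (e.g. `4:12`) pools all k.
#' @param trials_per_k number of randomized trials per k (default 100).
#' @param support_threshold co-clustering support needed for a network edge
#'   (default 0.90).
#' @param min_cluster_size smallest reported cluster (default 10 scaffolds).
#' @param seed master seed; every trial seed is derived from it.
#' @return Object of class `consensus_config`.
#' @export
consensus_config <- function(min_scaffold_length = 10000L, k_values = 8L,
                             trials_per_k = 100L, support_threshold = 0.90,
                             min_cluster_size = 10L, seed = 1L) {
  k_values <- sort(unique(as.integer(k_values)))
  stopifnot(all(k_values >= 2), trials_per_k >= 1,
            support_threshold > 0, support_threshold <= 1,
            min_cluster_size >= 1, min_scaffold_length >= 0)
  structure(list(min_scaffold_length = as.integer(min_scaffold_length),
                 k_values = k_values, trials_per_k = as.integer(trials_per_k),
                 support_threshold = support_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Drop scaffolds shorter than a length threshold
#'
#' @param x a [scaffold_set].
#' @param min_scaffold_length inclusive minimum length in bases.
#' @return The filtered `scaffold_set`, with attributes `n_kept` and
#'   `n_dropped`. Warns if nothing survives.
#' @export
filter_scaffolds <- function(x, min_scaffold_length = 10000L) {
  stopifnot(inherits(x, "scaffold_set"))
  keep <- Biostrings::width(x$seq) >= min_scaffold_length
  out <- x[which(keep)]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  message(sprintf("filter_scaffolds: kept %d, dropped %d (min length %d bp)",
                  sum(keep), sum(!keep), as.integer(min_scaffold_length)))
  if (!sum(keep)) warning("no scaffolds pass the length filter")
  out
}

## squared Euclidean distances between rows of X and rows of C
.sqdist <- function(X, C, xs2 = rowSums(X^2)) {
  d <- outer(xs2, rowSums(C^2), "+") - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

## k-means++ seeding: far-apart data points, D^2-weighted
.kmeanspp_init <- function(X, k, xs2) {
  n <- nrow(X)
  cs <- integer(k)
  cs[1] <- sample.int(n, 1)
  d2 <- drop(.sqdist(X, X[cs[1], , drop = FALSE], xs2))
  if (k > 1) for (j in 2:k) {
    cs[j] <- if (all(d2 <= 0)) sample.int(n, 1)
             else sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, drop(.sqdist(X, X[cs[j], , drop = FALSE], xs2)))
  }
  X[cs, , drop = FALSE]
}

#' One randomized k-means trial
#'
#' Euclidean Lloyd iteration from a k-means++ initialization governed solely
#' by `trial_seed`; fully deterministic for a fixed `(features, k,
#' trial_seed)`. Assignment ties break to the lowest cluster index; a cluster
#' emptied during iteration is re-seeded from the point farthest from its
#' current center.
#'
#' @param features numeric matrix, one scaffold per row.
#' @param k number of clusters (`2 <= k <= nrow(features)`).
#' @param trial_seed integer seed for this trial.
#' @param max_iter Lloyd iteration cap.
#' @return Integer label vector in `1..k`.
#' @export
kmeans_trial <- function(features, k, trial_seed, max_iter = 100L) {
  X0 <- as.matrix(features)
  n <- nrow(X0)
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")")
  if (!all(is.finite(X0))) stop("features must be finite")
  # run in a canonical row order so the seeded draws attach to points, not
  # to input positions: permuting the rows then permutes the labels
  co <- order(rowSums(X0), X0[, 1], X0[, min(2, ncol(X0))])
  X <- X0[co, , drop = FALSE]
  xs2 <- rowSums(X^2)
  out <- with_seed(trial_seed, {
    C <- .kmeanspp_init(X, k, xs2)
    a <- integer(n)
    for (it in seq_len(max_iter)) {
      D <- .sqdist(X, C, xs2)
      a_new <- max.col(-D, ties.method = "first")
      for (j in seq_len(k)) {
        if (any(a_new == j)) {
          C[j, ] <- colMeans(X[a_new == j, , drop = FALSE])
        } else { # re-seed empty cluster from the farthest point
          far <- which.max(D[cbind(seq_len(n), a_new)])
          C[j, ] <- X[far, ]
          a_new[far] <- j
        }
      }
      if (identical(a_new, a)) break
      a <- a_new
    }
    a
  })
  out[order(co)] # back to input order
}

#' Monte-Carlo consensus clustering of composition features
#'
#' Runs `trials_per_k` independently seeded k-means trials for every k in
#' `config$k_values`, accumulates the pairwise co-clustering support matrix,
#' and demarcates clusters via [extract_clusters()].
#'
#' @param features numeric matrix of composition frequencies (rows =
#'   scaffolds, rownames used as ids) or the result of
#'   [composition_matrix()].
#' @param config a [consensus_config()].
#' @return Object of class `cocluster_result`: list with `ids`, `support`
#'   (symmetric matrix, unit diagonal), `clusters` (list of id vectors,
#'   largest first), `unbinned` (ids in components smaller than
#'   `min_cluster_size`), `runs_executed`, and `config`.
#' @export
consensus <- function(features, config = consensus_config()) {
  if (is.list(features) && !is.null(features$freq)) features <- features$freq
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < max(config$k_values))
    stop("need at least max(k_values) = ", max(config$k_values),
         " scaffolds, got ", n)
  ids <- rownames(X) %||% as.character(seq_len(n))
  S <- matrix(0, n, n)
  runs <- 0L
  for (k in config$k_values) {
    for (trial in seq_len(config$trials_per_k)) {
      a <- kmeans_trial(X, k, derive_seed(config$seed, k, trial))
      S <- S + outer(a, a, "==")
      runs <- runs + 1L
    }
  }
  S <- S / runs
  dimnames(S) <- list(ids, ids)
  cl <- extract_clusters(S, config$support_threshold, config$min_cluster_size)
  structure(list(ids = ids, support = S, clusters = cl$clusters,
                 unbinned = cl$unbinned, runs_executed = runs,
                 config = config),
            class = "cocluster_result")
}

#' @export
print.cocluster_result <- function(x, ...) {
  cat(sprintf(paste0("cocluster_result: %d scaffolds, %d runs, %d clusters ",
                     "(support >= %.2f, min size %d), %d unbinned\n"),
              length(x$ids), x$runs_executed, length(x$clusters),
              x$config$support_threshold, x$config$min_cluster_size,
              length(x$unbinned)))
  invisible(x)
}

#' Demarcate clusters from a support matrix
#'
#' Builds a graph with an edge wherever pairwise support meets `threshold`
#' and reports connected components with at least `min_cluster_size` members;
#' smaller components are returned as unbinned.
#'
#' @param support symmetric support matrix with entries in `[0, 1]`.
#' @param threshold support threshold in `(0, 1]`.
#' @param min_cluster_size smallest component reported as a cluster.
#' @return List with `clusters` (list of member id vectors, ordered by
#'   decreasing size) and `unbinned` (vector of ids).
#' @export
extract_clusters <- function(support, threshold = 0.90,
                             min_cluster_size = 10L) {
  S <- as.matrix(support)
  stopifnot(nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) stop("support matrix must be symmetric")
  ids <- rownames(S) %||% as.character(seq_len(nrow(S)))
  adj <- (S >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  big <- groups[vapply(groups, length, 0L) >= min_cluster_size]
  big <- big[order(vapply(big, length, 0L), decreasing = TRUE)]
  names(big) <- NULL
  small <- groups[vapply(groups, length, 0L) < min_cluster_size]
  list(clusters = big, unbinned = unname(unlist(small)) %||% character(0))
}

#' Cluster assignment vector
#' @param result a `cocluster_result`.
#' @return Named integer vector mapping scaffold id to cluster number
#'   (`NA` for unbinned scaffolds).
#' @export
cluster_assignments <- function(result) {
  stopifnot(inherits(result, "cocluster_result"))
  out <- setNames(rep(NA_integer_, length(result$ids)), result$ids)
  for (i in seq_along(result$clusters)) out[result$clusters[[i]]] <- i
  out
}

#' Support network edge list at a threshold
#' @param result a `cocluster_result`.
#' @param threshold minimum support for an edge (defaults to the configured
#'   support threshold).
#' @return data.frame with columns `from`, `to`, `support`, suitable for
#'   [write_graph_file()].
#' @export
support_edges <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "cocluster_result"))
  threshold <- threshold %||% result$config$support_threshold
  S <- result$support
  idx <- which(upper.tri(S) & S >= threshold, arr.ind = TRUE)
  data.frame(from = result$ids[idx[, 1]], to = result$ids[idx[, 2]],
             support = S[idx], stringsAsFactors = FALSE)
}

#' Summary statistics for one cluster
#'
#' Per-cluster properties in the conventional report units: scaffold count,
#' median length (kb), mean and SD of G+C percent (sample SD, n-1), total
#' sequence (Mb), coverage mean/SD when every member is annotated, site
#' composition, and the majority taxon label if any member carries one.
#'
#' @param members a [scaffold_set] holding the cluster members.
#' @return One-row data.frame (list column `sites` holds the site counts).
#' @export
summarize_cluster <- function(members) {
  stopifnot(inherits(members, "scaffold_set"), length(members) >= 1)
  len <- Biostrings::width(members$seq)
  gc <- gc_content(members) * 100
  cov <- members$meta$coverage
  tx <- members$meta$taxon[!is.na(members$meta$taxon)]
  data.frame(
    n_scaffolds = length(len),
    median_size_kb = median(len) / 1000,
    mean_gc_pct = mean(gc),
    sd_gc_pct = if (length(gc) > 1) sd(gc) else 0,
    total_sequence_mb = sum(len) / 1e6,
    mean_coverage = if (all(!is.na(cov))) mean(cov) else NA_real_,
    sd_coverage = if (all(!is.na(cov)) && length(cov) > 1) sd(cov) else
      if (all(!is.na(cov))) 0 else NA_real_,
    taxon = if (length(tx)) names(which.max(table(tx))) else NA_character_,
    sites = I(list(table(members$meta$site))),
    stringsAsFactors = FALSE
  )
}

#' Cluster property table for a consensus result
#'
#' @param result a `cocluster_result`.
#' @param x the [scaffold_set] the features were computed from.
#' @return data.frame with one row per cluster (largest first) plus a
#'   `cluster` index and `sites` label column.
#' @export
summarize_clusters <- function(result, x) {
  stopifnot(inherits(result, "cocluster_result"), inherits(x, "scaffold_set"))
  rows <- lapply(seq_along(result$clusters), function(i) {
    s <- summarize_cluster(x[result$clusters[[i]]])
    sites <- s$sites[[1]]
    s$sites <- paste(sprintf("%s:%d", names(sites), as.integer(sites)),
                     collapse = ",")
    cbind(cluster = i, s)
  })
  do.call(rbind, rows)
}
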