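## ecostats: Gower dissimilarity of mixed environmental variables,
## permutation-based vector fitting onto ordination scores, and
## alpha-diversity estimators with analytic rarefaction.

#' Parse numeric environmental values with detection limits
#'
#' Field tables often report values below the detection limit as `"<x"`;
#' these are replaced by `x / 2` (a conventional midpoint substitution) and
#' `"nd"`/empty entries become `NA`. The positions substituted are recorded
#' in attribute `below_detection`.
#'
#' @param x character (or numeric) vector.
#' @return Numeric vector with attribute `below_detection`.
#' @export
#' @examples
#' parse_env_values(c("117", "<3", "nd"))
parse_env_values <- function(x) {
  if (is.numeric(x)) {
    out <- x
    attr(out, "below_detection") <- rep(FALSE, length(x))
    return(out)
  }
  x <- trimws(as.character(x))
  bdl <- grepl("^<", x)
  out <- suppressWarnings(as.numeric(x))
  out[bdl] <- suppressWarnings(as.numeric(sub("^<", "", x[bdl]))) / 2
  out[x %in% c("nd", "ND", "na", "NA", "")] <- NA_real_
  attr(out, "below_detection") <- bdl
  out
}

#' Gower dissimilarity of mixed-type site variables
#'
#' For sites i, j: `d(i,j) = sum_v w_v * delta_v / sum_v w_v`, where for a
#' numeric variable `delta = |x_i - x_j| / range(v)` and for a categorical
#' variable `delta = 0` if equal else 1. A variable gets weight 0 for a pair
#' when either value is missing or (numeric) its range is zero.
#'
#' @param env data.frame of site rows; numeric columns are treated as
#'   quantitative, everything else as categorical. Row names are site ids.
#' @return Symmetric site x site matrix with zero diagonal, entries in
#'   `[0, 1]`. Errors if some pair shares no comparable variable.
#' @export
gower_distance <- function(env) {
  stopifnot(is.data.frame(env), nrow(env) >= 2)
  if (!all(vapply(env, function(v) any(!is.na(v)), TRUE)))
    stop("every variable needs at least one non-missing value")
  n <- nrow(env)
  ids <- rownames(env) %||% as.character(seq_len(n))
  num <- vapply(env, is.numeric, TRUE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  W <- matrix(0, n, n)
  for (v in seq_along(env)) {
    x <- env[[v]]
    ok <- !is.na(x)
    wv <- outer(ok, ok, "&")
    if (num[v]) {
      rg <- diff(range(x, na.rm = TRUE))
      if (rg == 0) next # zero-range variable carries no information
      dv <- abs(outer(x, x, "-")) / rg
    } else {
      x <- as.character(x)
      dv <- outer(x, x, "!=") * 1
    }
    dv[!wv] <- 0
    D <- D + dv
    W <- W + wv
  }
  diag(W) <- pmax(diag(W), 1)
  if (any(W == 0)) {
    bad <- sort(which(W == 0, arr.ind = TRUE)[1, ])
    stop("sites ", ids[bad[1]], " and ", ids[bad[2]],
         " share no comparable variable")
  }
  out <- D / W
  diag(out) <- 0
  out
}

#' Fit environmental variables onto ordination scores
#'
#' For each variable, measures how much of its variation aligns with the
#' ordination: a numeric variable is regressed onto the score space and
#' scored by the squared multiple correlation; a categorical variable is
#' scored by the among-centroid fraction of the total score sum of squares.
#' Significance comes from permuting the variable across sites:
#' `p = (1 + #permuted r2 >= observed) / (1 + n_permutations)`.
#'
#' @param scores samples x axes matrix (e.g. `pcoa(gower_distance(env))$scores`).
#' @param env data.frame of variables, rows aligned with `scores`.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class `envfit_result` with columns `variable`,
#'   `type`, `r2`, `p_value`, `n_used`; attribute `directions` holds unit
#'   direction vectors for numeric variables and `centroids` holds factor
#'   level centroids.
#' @export
fit_env_variables <- function(scores, env, n_permutations = 999, seed = 1) {
  S <- as.matrix(scores)
  stopifnot(is.data.frame(env), nrow(env) == nrow(S))
  if (nrow(S) < ncol(S) + 1)
    stop("need more sites than ordination axes")
  dirs <- list()
  cents <- list()
  rows <- lapply(names(env), function(nm) {
    x <- env[[nm]]
    ok <- !is.na(x)
    n_used <- sum(ok)
    Sc <- scale(S[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    seed_v <- derive_seed(seed, match(nm, names(env)))
    if (is.numeric(x)) {
      y <- x[ok]
      if (var(y) == 0) {
        message("variable '", nm, "' is constant; r2 = 0")
        return(data.frame(variable = nm, type = "numeric", r2 = 0,
                          p_value = NA_real_, n_used = n_used))
      }
      qrS <- qr(Sc)
      Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
      r2_of <- function(Y) { # columns = candidate y vectors
        Yc <- sweep(Y, 2, colMeans(Y))
        colSums((crossprod(Q, Yc))^2) / colSums(Yc^2)
      }
      r2 <- r2_of(cbind(y))
      b <- qr.coef(qrS, y - mean(y))
      b[is.na(b)] <- 0
      dirs[[nm]] <<- if (sum(b^2) > 0) b / sqrt(sum(b^2)) else b
      perm <- with_seed(seed_v, replicate(n_permutations, sample(y)))
      p <- (1 + sum(r2_of(perm) >= r2)) / (1 + n_permutations)
      data.frame(variable = nm, type = "numeric", r2 = unname(r2),
                 p_value = p, n_used = n_used)
    } else {
      g <- factor(x[ok])
      if (nlevels(g) < 2) {
        message("variable '", nm, "' is constant; r2 = 0")
        return(data.frame(variable = nm, type = "factor", r2 = 0,
                          p_value = NA_real_, n_used = n_used))
      }
      tot <- sum(Sc^2)
      r2_of <- function(gg) {
        cen <- apply(Sc, 2, function(col) tapply(col, gg, mean))
        within <- sum((Sc - cen[as.integer(gg), , drop = FALSE])^2)
        if (tot > 0) 1 - within / tot else 0
      }
      r2 <- r2_of(g)
      cen <- apply(Sc, 2, function(col) tapply(col, g, mean))
      cents[[nm]] <<- cen
      pr2 <- with_seed(seed_v, vapply(seq_len(n_permutations),
                                      function(i) r2_of(sample(g)), 0))
      p <- (1 + sum(pr2 >= r2)) / (1 + n_permutations)
      data.frame(variable = nm, type = "factor", r2 = r2,
                 p_value = p, n_used = n_used)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "directions") <- dirs
  attr(out, "centroids") <- cents
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("envfit_result", "data.frame")
  out
}

.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("need at least one individual")
  counts
}

#' Chao1 species-richness estimator
#'
#' `S_obs + f1^2 / (2 f2)` from singleton (`f1`) and doubleton (`f2`)
#' counts; when `f2 = 0` the bias-corrected form
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` is used.
#'
#' @param counts vector of per-species abundances (zeros ignored).
#' @return Estimated richness (>= observed richness).
#' @export
#' @examples
#' chao1(c(1, 1, 2)) # 3 + 4/2 = 5
chao1 <- function(counts) {
  n <- .check_counts(counts)
  s_obs <- length(n)
  f1 <- sum(n == 1)
  f2 <- sum(n == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2
}

#' ACE species-richness estimator
#'
#' Abundance-based coverage estimator with the conventional rare/abundant
#' cut: `S_abund + S_rare / C + (f1 / C) * gamma^2`, where
#' `C = 1 - f1 / N_rare` is the sample coverage of rare species and
#' `gamma^2` the (floored at 0) squared coefficient of variation of rare
#' abundances. Falls back to [chao1()] with a message when every rare
#' species is a singleton (`C = 0`).
#'
#' @param counts vector of per-species abundances.
#' @param rare_threshold abundance at or below which a species is "rare"
#'   (default 10).
#' @return Estimated richness; attribute `method` is `"ace"` or
#'   `"chao1_fallback"`.
#' @export
ace <- function(counts, rare_threshold = 10) {
  n <- .check_counts(counts)
  s_obs <- length(n)
  rare <- n[n <= rare_threshold]
  s_abund <- sum(n > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(structure(s_obs, method = "ace"))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0 || n_rare <= 1) {
    message("all rare species are singletons; falling back to chao1")
    return(structure(chao1(counts), method = "chao1_fallback"))
  }
  f <- tabulate(rare, nbins = rare_threshold)
  g2 <- max(s_rare / c_ace * sum(seq_len(rare_threshold) *
                                   (seq_len(rare_threshold) - 1) * f) /
              (n_rare * (n_rare - 1)) - 1, 0)
  structure(s_abund + s_rare / c_ace + f1 / c_ace * g2, method = "ace")
}

#' Shannon diversity index
#' @param counts per-species abundances.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return `H = -sum p_i log p_i`.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  n <- .check_counts(counts)
  p <- n / sum(n)
  -sum(p * log(p)) / log(base)
}

#' Reciprocal Simpson diversity
#'
#' Inverse probability that two randomly drawn individuals are conspecific
#' (proportion form): `1 / sum p_i^2`. An "effective species number" in
#' `[1, S_obs]`.
#'
#' @param counts per-species abundances.
#' @return Reciprocal Simpson index.
#' @export
simpson_reciprocal <- function(counts) {
  n <- .check_counts(counts)
  p <- n / sum(n)
  1 / sum(p^2)
}

#' Fisher's alpha of the log-series abundance model
#'
#' Solves `S = alpha * ln(1 + N / alpha)` for `alpha` by bracketed
#' root-finding followed by Newton polishing to residual below 1e-9.
#'
#' @param counts per-species abundances.
#' @return Fisher's alpha; `Inf` (with a warning) when every species is a
#'   singleton, where the log-series likelihood is unbounded.
#' @export
fisher_alpha <- function(counts) {
  n <- .check_counts(counts)
  s <- length(n)
  N <- sum(n)
  if (s == N) {
    warning("all species are singletons; fisher alpha diverges")
    return(Inf)
  }
  f <- function(a) a * log1p(N / a) - s
  a <- uniroot(f, c(1e-12, 1e12), tol = 1e-10)$root
  for (i in 1:50) { # Newton polish
    res <- f(a)
    if (abs(res) < 1e-12) break
    a <- a - res / (log1p(N / a) - N / (a + N))
  }
  a
}

#' Analytic rarefaction curve
#'
#' Expected species count in a random subsample of `m` individuals, computed
#' hypergeometrically: `E[S_m] = sum_i (1 - C(N - n_i, m) / C(N, m))`.
#'
#' @param counts per-species abundances.
#' @param depths vector of subsample sizes, each `<= N`.
#' @return data.frame with columns `depth` and `expected_s`.
#' @export
rarefaction <- function(counts, depths) {
  n <- .check_counts(counts)
  N <- sum(n)
  depths <- as.integer(depths)
  if (any(depths < 1) || any(depths > N))
    stop("depths must lie in [1, total count N = ", N, "]")
  es <- vapply(depths, function(m) {
    sum(1 - exp(lchoose(N - n, m) - lchoose(N, m)))
  }, 0)
  data.frame(depth = depths, expected_s = es)
}

#' Alpha-diversity report for one sample
#'
#' Computes observed richness, Chao1, ACE, Shannon (nats), reciprocal
#' Simpson, Fisher's alpha and an analytic rarefaction curve.
#'
#' @param counts per-species abundances.
#' @param depths rarefaction depths (default: 20 levels up to N).
#' @return List of class `diversity_report`.
#' @export
diversity_report <- function(counts, depths = NULL) {
  n <- .check_counts(counts)
  N <- sum(n)
  depths <- depths %||% unique(pmax(1, round(seq(1, N, length.out = 20))))
  structure(list(
    s_obs = length(n),
    chao1 = chao1(n),
    ace = as.numeric(ace(n)),
    shannon = shannon_index(n),
    simpson_reciprocal = simpson_reciprocal(n),
    fisher_alpha = if (length(n) < N) fisher_alpha(n) else Inf,
    rarefaction = rarefaction(n, depths)
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(paste0("diversity_report: S_obs %d, chao1 %.1f, ACE %.1f, ",
                     "H' %.3f, 1/lambda %.2f, Fisher alpha %.2f\n"),
              x$s_obs, x$chao1, x$ace, x$shannon, x$simpson_reciprocal,
              x$fisher_alpha))
  invisible(x)
}
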