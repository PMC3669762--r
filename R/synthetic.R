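## synthetic_data: generators for every input the pipeline consumes, with
## planted structure and truth tables.
##
## Genome models are order-m Markov chains over ACGT whose conditional
## distributions all emit G+C with exactly the target probability, so the
## stationary G+C equals the target while the higher-order word statistics
## (the 3-6-mer signature the binning exploits) differ between models.

BASE_CODES <- c("A", "C", "G", "T")

#' Sample a random genome composition model
#'
#' Builds an order-`markov_order` Markov chain whose per-context conditional
#' nucleotide distributions are a base distribution (G+C split evenly between
#' G and C, A+T between A and T) perturbed multiplicatively by
#' `bias_strength` on the log scale, then renormalized within the G/C and
#' A/T pairs so every context emits G+C with probability `target_gc`
#' exactly. Two models with identical `target_gc` thus still differ in
#' higher-order word composition whenever `bias_strength > 0`.
#'
#' @param target_gc stationary G+C fraction, in (0, 1).
#' @param markov_order chain order (0 = i.i.d. bases), at most 5.
#' @param bias_strength SD of the log-normal perturbation (0 = no bias).
#' @param seed integer seed; the same seed reproduces identical weights.
#' @param label model label carried into truth tables.
#' @return Object of class `genome_model` with the transition matrix
#'   (`4^order` contexts x 4 bases) and the initial base distribution.
#' @export
sample_genome_model <- function(target_gc, markov_order = 2L,
                                bias_strength = 0.5, seed = 1L,
                                label = sprintf("gc%02.0f", target_gc * 100)) {
  stopifnot(target_gc > 0, target_gc < 1, markov_order >= 0,
            markov_order <= 5, bias_strength >= 0)
  base <- c((1 - target_gc) / 2, target_gc / 2, target_gc / 2,
            (1 - target_gc) / 2)
  nctx <- 4^markov_order
  trans <- with_seed(seed, {
    P <- matrix(0, nctx, 4)
    for (i in seq_len(nctx)) {
      w <- base * exp(bias_strength * rnorm(4))
      w[c(2, 3)] <- w[c(2, 3)] / sum(w[c(2, 3)]) * target_gc
      w[c(1, 4)] <- w[c(1, 4)] / sum(w[c(1, 4)]) * (1 - target_gc)
      P[i, ] <- w
    }
    P
  })
  colnames(trans) <- BASE_CODES
  structure(list(label = label, target_gc = target_gc,
                 markov_order = as.integer(markov_order),
                 bias_strength = bias_strength, trans = trans,
                 base_probs = base, seed = as.integer(seed)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model '%s': order %d, target G+C %.0f%%, bias %.2f\n",
              x$label, x$markov_order, 100 * x$target_gc, x$bias_strength))
  invisible(x)
}

## stationary distribution over contexts of an order->=1 chain
.stationary_contexts <- function(model) {
  o <- model$markov_order
  if (o == 0) return(1)
  nctx <- 4^o
  Tm <- matrix(0, nctx, nctx)
  for (i in seq_len(nctx)) {
    for (b in 1:4) {
      j <- ((i - 1) %% 4^(o - 1)) * 4 + b
      Tm[i, j] <- Tm[i, j] + model$trans[i, b]
    }
  }
  ev <- Re(eigen(t(Tm))$vectors[, 1])
  ev / sum(ev)
}

#' Exact word probabilities under a genome model
#'
#' Stationary probability of every length-`k` word (requires
#' `k >= markov_order`); useful as an analytic oracle for the composition
#' and binning machinery.
#'
#' @param model a `genome_model`.
#' @param k word length.
#' @return Named numeric vector over the `4^k` words, summing to 1.
#' @export
model_word_probs <- function(model, k) {
  o <- model$markov_order
  stopifnot(k >= max(o, 1))
  pi0 <- .stationary_contexts(model)
  words <- Biostrings::mkAllStrings(BASE_CODES, k)
  codes <- t(vapply(strsplit(words, ""),
                    function(w) match(w, BASE_CODES), integer(k)))
  pr <- numeric(length(words))
  for (r in seq_along(words)) {
    w <- codes[r, ]
    if (o == 0) {
      pr[r] <- prod(model$base_probs[w])
    } else {
      ctx <- sum((w[seq_len(o)] - 1) * 4^((o - 1):0)) + 1
      p <- pi0[ctx]
      if (k > o) for (t in (o + 1):k) {
        p <- p * model$trans[ctx, w[t]]
        ctx <- ((ctx - 1) %% 4^(o - 1)) * 4 + w[t]
      }
      pr[r] <- p
    }
  }
  setNames(pr, words)
}

#' Expected stationary G+C of a genome model
#' @param model a `genome_model`.
#' @return Expected G+C fraction (equals `target_gc` by construction).
#' @export
model_gc <- function(model) {
  pi0 <- .stationary_contexts(model)
  sum(pi0 * (model$trans[, "C"] + model$trans[, "G"]))
}

#' Specify a synthetic community
#'
#' @param models list of [sample_genome_model()] results.
#' @param abundances relative abundances (recycled/normalized; default
#'   equal).
#' @param n_scaffolds either a single total (models drawn per scaffold by
#'   `abundances`) or a vector of exact per-model scaffold counts.
#' @param length_median,length_sigma lognormal scaffold-length parameters
#'   (median in bases; sigma on the log scale).
#' @param length_range truncation bounds in bases, defaults 1 kb to 130 kb,
#'   matching the span of real mat-community assemblies.
#' @param n_rate per-base probability of masking with `N` (default 0).
#' @param site site label stamped on generated scaffolds.
#' @param seed integer seed.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(models, abundances = NULL, n_scaffolds = 180L,
                           length_median = 15000, length_sigma = 0.7,
                           length_range = c(1000, 130000), n_rate = 0,
                           site = "synthetic", seed = 1L) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "genome_model")))
  abundances <- abundances %||% rep(1, length(models))
  stopifnot(length(abundances) == length(models), all(abundances > 0))
  abundances <- abundances / sum(abundances)
  stopifnot(length_range[1] >= 1, length_range[2] >= length_range[1],
            n_rate >= 0, n_rate < 1,
            length(n_scaffolds) %in% c(1L, length(models)))
  structure(list(models = models, abundances = abundances,
                 n_scaffolds = as.integer(n_scaffolds),
                 length_median = length_median, length_sigma = length_sigma,
                 length_range = length_range, n_rate = n_rate, site = site,
                 seed = as.integer(seed)),
            class = "community_spec")
}

## truncated lognormal lengths by rejection
.sample_lengths <- function(n, median, sigma, range) {
  if (sigma == 0) return(rep(round(median), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2 * (n - length(out)) + 10, meanlog = log(median),
                sdlog = sigma)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  round(out[seq_len(n)])
}

.sample_sequence <- function(model, len) {
  o <- model$markov_order
  init <- if (o > 0) {
    sample.int(4, o, replace = TRUE, prob = model$base_probs) - 1L
  } else integer(0)
  cum <- t(apply(model$trans, 1, cumsum))
  if (model$markov_order == 0) cum <- matrix(cum, nrow = 1)
  codes <- markov_chain_sample(cum, o, as.integer(len), init)
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

#' Generate a synthetic scaffold collection with planted labels
#'
#' Draws each scaffold's source model by relative abundance, its length from
#' the truncated lognormal, and its sequence from the model's Markov chain.
#' A truth table always accompanies the records.
#'
#' @param spec a [community_spec()].
#' @return List with `records` (a [scaffold_set]; taxon = planted model
#'   label) and `truth` (data.frame `id`, `label`, `length`).
#' @export
generate_scaffolds <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    if (length(spec$n_scaffolds) > 1) { # exact per-model composition
      n <- sum(spec$n_scaffolds)
      which_model <- rep(seq_along(spec$models), spec$n_scaffolds)
    } else {
      n <- spec$n_scaffolds
      which_model <- sample.int(length(spec$models), n, replace = TRUE,
                                prob = spec$abundances)
    }
    lens <- .sample_lengths(n, spec$length_median, spec$length_sigma,
                            spec$length_range)
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- .sample_sequence(spec$models[[which_model[i]]], lens[i])
      if (spec$n_rate > 0) {
        mask <- which(runif(lens[i]) < spec$n_rate)
        if (length(mask)) {
          sv <- strsplit(s, "")[[1]]
          sv[mask] <- "N"
          s <- paste(sv, collapse = "")
        }
      }
      seqs[i] <- s
    }
    ids <- sprintf("scf%05d", seq_len(n))
    labels <- vapply(spec$models, `[[`, "", "label")[which_model]
    names(seqs) <- ids
    records <- scaffold_set(seqs, site = spec$site, taxon = labels)
    list(records = records,
         truth = data.frame(id = ids, label = labels, length = lens,
                            stringsAsFactors = FALSE))
  })
}

#' Generate synthetic OTU counts from a species-abundance model
#'
#' `"logseries"` samples N individuals sequentially with new-species
#' probability `alpha / (alpha + i - 1)` (the urn process whose expected
#' richness is `alpha ln(1 + N / alpha)`, i.e. the model under which
#' Fisher's alpha is consistent). `"lognormal"` draws `S_true` lognormal
#' relative abundances and a multinomial sample of N individuals.
#'
#' @param S_true species-pool size (lognormal mode; in logseries mode used
#'   only to derive `alpha` when that is not given).
#' @param N number of individuals sampled.
#' @param abundance_model `"logseries"` or `"lognormal"`.
#' @param seed integer seed.
#' @param alpha Fisher's alpha of the log-series (logseries mode).
#' @param sdlog SD of log relative abundances (lognormal mode, default 1).
#' @return Named integer vector of per-OTU counts.
#' @export
generate_otu_counts <- function(S_true = NULL, N,
                                abundance_model = c("logseries", "lognormal"),
                                seed = 1L, alpha = NULL, sdlog = 1) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(N >= 1)
  counts <- with_seed(seed, {
    if (abundance_model == "logseries") {
      if (is.null(alpha)) {
        if (is.null(S_true) || S_true >= N)
          stop("logseries mode needs 'alpha', or S_true < N to derive it")
        alpha <- uniroot(function(a) a * log1p(N / a) - S_true,
                         c(1e-10, 1e10), tol = 1e-10)$root
      }
      cnt <- integer(0)
      for (i in seq_len(N)) {
        if (runif(1) < alpha / (alpha + i - 1)) {
          cnt <- c(cnt, 1L)
        } else {
          j <- sample.int(length(cnt), 1, prob = cnt)
          cnt[j] <- cnt[j] + 1L
        }
      }
      cnt
    } else {
      stopifnot(!is.null(S_true), S_true >= 1)
      p <- rlnorm(S_true, 0, sdlog)
      drop(rmultinom(1, N, p / sum(p)))
    }
  })
  setNames(as.integer(counts), sprintf("otu_%04d", seq_along(counts)))
}

#' Generate a synthetic environmental matrix with a planted gradient
#'
#' Sites lie on a latent gradient; the first numeric variable tracks it with
#' strength `effect_axis` (0 = pure noise, the null world), remaining
#' numeric variables are independent noise, and factors are random levels.
#'
#' @param n_sites number of sites.
#' @param n_numeric,n_factor numbers of numeric / categorical variables.
#' @param effect_axis gradient strength of the planted variable, in noise-SD
#'   units per unit gradient (noise SD is 0.5).
#' @param seed integer seed.
#' @param n_levels factor levels.
#' @return data.frame of class `env_matrix` (sites in rows); attribute
#'   `truth` holds the latent `gradient` and the `planted` variable name
#'   (`NA` if `effect_axis == 0`).
#' @export
generate_env_matrix <- function(n_sites, n_numeric = 5L, n_factor = 2L,
                                effect_axis = 1, seed = 1L, n_levels = 3L) {
  stopifnot(n_sites >= 2, n_numeric >= 1)
  with_seed(seed, {
    g <- seq(-1, 1, length.out = n_sites)
    env <- as.data.frame(matrix(rnorm(n_sites * n_numeric, sd = 0.5),
                                n_sites, n_numeric))
    names(env) <- sprintf("env%02d", seq_len(n_numeric))
    env$env01 <- env$env01 + effect_axis * g
    for (f in seq_len(n_factor)) {
      env[[sprintf("fac%02d", f)]] <-
        sample(LETTERS[seq_len(n_levels)], n_sites, replace = TRUE)
    }
    rownames(env) <- sprintf("site_%02d", seq_len(n_sites))
    attr(env, "truth") <- list(gradient = g,
                               planted = if (effect_axis != 0) "env01"
                                         else NA_character_)
    class(env) <- c("env_matrix", "data.frame")
    env
  })
}

#' Generate a synthetic functional-category matrix with planted site groups
#'
#' Category baselines are lognormal; each planted site group shifts every
#' category's log-mean by a group-specific offset drawn `N(0,
#' effect_size^2)`, and counts are Poisson. Site groups are contiguous
#' blocks.
#'
#' @param n_sites,n_categories matrix dimensions (defaults 12 sites, 52
#'   categories, the conventional functional-category granularity).
#' @param n_groups number of planted site groups.
#' @param effect_size SD of the per-(group, category) log-mean offsets
#'   (default 1, i.e. typical e-fold shifts between groups).
#' @param seed integer seed.
#' @param base_mean baseline expected count per category per site.
#' @return Category x site integer matrix; attribute `truth` holds the site
#'   group labels.
#' @export
generate_func_matrix <- function(n_sites = 12L, n_categories = 52L,
                                 n_groups = 3L, effect_size = 1, seed = 1L,
                                 base_mean = 200) {
  stopifnot(n_sites >= n_groups, n_groups >= 1)
  with_seed(seed, {
    groups <- sort(rep_len(seq_len(n_groups), n_sites))
    base <- rnorm(n_categories, log(base_mean), 1)
    offs <- matrix(rnorm(n_categories * n_groups, 0, effect_size),
                   n_categories, n_groups)
    lam <- exp(base + offs[, groups, drop = FALSE])
    m <- matrix(rpois(length(lam), lam), n_categories, n_sites,
                dimnames = list(sprintf("cat_%03d", seq_len(n_categories)),
                                sprintf("site_%02d", seq_len(n_sites))))
    attr(m, "truth") <- list(groups = setNames(groups, colnames(m)))
    m
  })
}
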