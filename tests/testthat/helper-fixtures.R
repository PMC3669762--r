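## Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(len, with_n = FALSE, seed = NULL) {
  draw <- function() {
    alph <- c("A", "C", "G", "T")
    s <- sample(alph, len, replace = TRUE)
    if (with_n) s[sample(len, max(1, len %/% 15))] <- "N"
    paste(s, collapse = "")
  }
  if (is.null(seed)) draw() else matbin:::with_seed(seed, draw())
}

## brute-force sliding-window word counter (independent of Biostrings)
naive_count_oligos <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  counts <- integer(0)
  valid <- 0L
  if (length(chars) >= k) {
    for (i in seq_len(length(chars) - k + 1)) {
      w <- chars[i:(i + k - 1)]
      if (all(w %in% c("A", "C", "G", "T"))) {
        valid <- valid + 1L
        word <- paste(w, collapse = "")
        counts[word] <- (if (word %in% names(counts)) counts[word] else 0L) + 1L
      }
    }
  }
  list(counts = counts, n_valid = valid)
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## scaffold_set with given lengths (poly-A bodies; for length-only tests)
dummy_scaffolds <- function(lengths) {
  scaffold_set(setNames(strrep("A", lengths),
                        sprintf("d%04d", seq_along(lengths))))
}

## three-population community at the stated world's scale
three_pop_community <- function(seed, gc = c(0.35, 0.50, 0.65), order = 2,
                                n_each = 60) {
  models <- lapply(seq_along(gc), function(i) {
    sample_genome_model(gc[i], markov_order = order, bias_strength = 0.5,
                        seed = derive_seed(seed, 100 + i),
                        label = sprintf("pop%d", i))
  })
  generate_scaffolds(community_spec(models, n_scaffolds = rep(n_each,
                                                              length(gc)),
                                    seed = derive_seed(seed, 200)))
}

## ARI between demarcated clusters and planted labels, over binned scaffolds
binned_ari <- function(result, truth) {
  asg <- cluster_assignments(result)
  lab <- setNames(truth$label, truth$id)[names(asg)]
  ok <- !is.na(asg)
  adjusted_rand_index(asg[ok], lab[ok])
}

## mean silhouette of points under given labels (euclidean)
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}
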