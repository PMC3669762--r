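## composition: oligonucleotide word frequencies and G+C statistics.
##
## Words of length k are counted in sliding windows of step 1; any window
## containing a non-ACGT symbol is skipped and excluded from the valid-window
## denominator, so per-k frequency vectors are exact probability simplices.

.as_dna <- function(sequence) {
  if (is.character(sequence)) Biostrings::DNAString(toupper(sequence))
  else sequence
}

#' G+C content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguous (non-ACGT) bases are excluded
#' from numerator and denominator. Returns `NA` when no unambiguous base
#' exists.
#'
#' @param sequence character string, `DNAString`, or a [scaffold_set] (in
#'   which case a named vector is returned).
#' @return G+C fraction in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' gc_content("ACGTN") # N excluded: 2/4
gc_content <- function(sequence) {
  if (inherits(sequence, "scaffold_set")) {
    af <- Biostrings::letterFrequency(sequence$seq, c("A", "C", "G", "T"))
    tot <- rowSums(af)
    out <- ifelse(tot > 0, (af[, "C"] + af[, "G"]) / tot, NA_real_)
    return(setNames(out, sequence$meta$id))
  }
  s <- .as_dna(sequence)
  if (length(s) == 0) stop("empty sequence")
  af <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  tot <- sum(af)
  if (tot == 0) return(NA_real_)
  unname((af["C"] + af["G"]) / tot)
}

## canonical-word fold: map each word to min(word, revcomp(word))
.canonical_map <- function(words) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  ifelse(words <= rc, words, rc)
}

#' Count oligonucleotide words in a sequence
#'
#' Counts all words of each length in `k_min:k_max`. Windows overlapping a
#' non-ACGT symbol are skipped. With `collapse_revcomp = TRUE` a word and its
#' reverse complement pool into one canonical key (the lexicographically
#' smaller of the pair).
#'
#' @param sequence character or `DNAString`.
#' @param k_min,k_max word length range (defaults 3 and 6).
#' @param collapse_revcomp pool reverse-complement pairs?
#' @return List with `counts` (named integer vector, all k concatenated) and
#'   `n_valid_windows` (named integer vector indexed by k). A k longer than
#'   the sequence yields zero counts, not an error.
#' @export
#' @examples
#' count_oligos("AAAA", k_min = 3, k_max = 3)$counts[["AAA"]]
count_oligos <- function(sequence, k_min = 3L, k_max = 6L,
                         collapse_revcomp = FALSE) {
  stopifnot(k_min >= 1, k_min <= k_max)
  s <- .as_dna(sequence)
  if (length(s) == 0) stop("empty sequence")
  ks <- seq.int(k_min, k_max)
  counts <- list()
  nvw <- integer(length(ks))
  names(nvw) <- as.character(ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    cnt <- if (length(s) < k) {
      setNames(integer(4^k),
               Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
    } else {
      Biostrings::oligonucleotideFrequency(s, width = k)
    }
    nvw[i] <- sum(cnt)
    if (collapse_revcomp) {
      can <- .canonical_map(names(cnt))
      cnt <- vapply(split(cnt, can), sum, 0L)
      cnt <- cnt[order(names(cnt))]
    }
    counts[[i]] <- cnt
  }
  list(counts = unlist(counts), n_valid_windows = nvw)
}

#' Normalize word counts to frequencies
#'
#' Divides each word count by the number of valid windows of its length, so
#' that frequencies of each word length sum to 1. A length with zero valid
#' windows yields an all-zero block, flagged in attribute `zero_k`.
#'
#' @param counts named count vector as produced by [count_oligos()].
#' @param n_valid_windows named per-k valid-window counts.
#' @return Named numeric vector of frequencies.
#' @export
normalize_oligos <- function(counts, n_valid_windows) {
  kl <- nchar(names(counts))
  denom <- n_valid_windows[as.character(kl)]
  freq <- ifelse(denom > 0, counts / denom, 0)
  zero <- as.integer(names(n_valid_windows)[n_valid_windows == 0])
  out <- setNames(as.numeric(freq), names(counts))
  if (length(zero)) attr(out, "zero_k") <- zero
  out
}

#' Composition vector for a single scaffold
#'
#' Bundles counts, length-normalized frequencies, G+C fraction and the
#' valid-window bookkeeping for one sequence.
#'
#' @inheritParams count_oligos
#' @param id scaffold id carried into the result.
#' @return Object of class `composition_vector`.
#' @export
composition_vector <- function(sequence, id = NA_character_, k_min = 3L,
                               k_max = 6L, collapse_revcomp = FALSE) {
  co <- count_oligos(sequence, k_min, k_max, collapse_revcomp)
  structure(list(id = id, k_range = c(k_min, k_max), counts = co$counts,
                 frequencies = normalize_oligos(co$counts, co$n_valid_windows),
                 gc = gc_content(sequence), n_valid_windows = co$n_valid_windows),
            class = "composition_vector")
}

#' Composition feature matrix for a scaffold collection
#'
#' Vectorized counterpart of [composition_vector()]: one row of normalized
#' word frequencies per scaffold (all word lengths concatenated; 5440 columns
#' for the default k = 3..6), plus per-scaffold G+C.
#'
#' @param x a [scaffold_set].
#' @inheritParams count_oligos
#' @return List with `freq` (scaffold x word matrix), `gc` (named vector),
#'   `n_valid_windows` (scaffold x k matrix) and `k_range`.
#' @export
composition_matrix <- function(x, k_min = 3L, k_max = 6L,
                               collapse_revcomp = FALSE) {
  stopifnot(inherits(x, "scaffold_set"), k_min >= 1, k_min <= k_max)
  ks <- seq.int(k_min, k_max)
  blocks <- vector("list", length(ks))
  nvw <- matrix(0L, length(x), length(ks),
                dimnames = list(x$meta$id, as.character(ks)))
  for (i in seq_along(ks)) {
    k <- ks[i]
    cnt <- Biostrings::oligonucleotideFrequency(x$seq, width = k)
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1,
                                         dimnames = list(NULL, names(cnt)))
    if (collapse_revcomp) {
      can <- .canonical_map(colnames(cnt))
      cnt <- t(rowsum(t(cnt), can))
      cnt <- cnt[, order(colnames(cnt)), drop = FALSE]
    }
    nv <- rowSums(cnt)
    nvw[, i] <- nv
    blocks[[i]] <- cnt / ifelse(nv > 0, nv, 1)
  }
  freq <- do.call(cbind, blocks)
  rownames(freq) <- x$meta$id
  list(freq = freq, gc = gc_content(x), n_valid_windows = nvw,
       k_range = c(k_min, k_max))
}

#' G+C frequency spectrum of a scaffold collection
#'
#' Histogram of per-sequence G+C percent over uniform bins covering
#' `[0, 100]`, optionally stratified by taxon label (sequences without a
#' label fall in stratum `"unassigned"`).
#'
#' @param x a [scaffold_set].
#' @param bin_width bin width in percent (default 1).
#' @param stratify_by_taxon build one stratum per distinct taxon label?
#' @return Object of class `gc_spectrum`: a strata x bin count matrix with
#'   attributes `bin_edges` and `bin_width`.
#' @export
gc_spectrum <- function(x, bin_width = 1, stratify_by_taxon = TRUE) {
  stopifnot(inherits(x, "scaffold_set"), bin_width > 0)
  gc <- gc_content(x) * 100
  if (anyNA(gc)) stop("sequences with undefined G+C (no unambiguous base)")
  edges <- seq(0, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  bin <- findInterval(gc, edges, rightmost.closed = TRUE)
  strata <- if (stratify_by_taxon) {
    tx <- x$meta$taxon
    ifelse(is.na(tx) | !nzchar(tx), "unassigned", tx)
  } else rep("all", length(gc))
  levs <- sort(unique(strata))
  counts <- matrix(0L, length(levs), length(edges) - 1L,
                   dimnames = list(levs, sprintf("[%g,%g)", edges[-length(edges)],
                                                 edges[-1])))
  for (i in seq_along(gc)) {
    counts[strata[i], bin[i]] <- counts[strata[i], bin[i]] + 1L
  }
  structure(counts, bin_edges = edges, bin_width = bin_width,
            class = c("gc_spectrum", class(counts)))
}

#' Mode of a G+C spectrum
#' @param spectrum a `gc_spectrum`.
#' @return Midpoint (percent G+C) of the bin with the highest total count.
#' @export
spectrum_mode <- function(spectrum) {
  stopifnot(inherits(spectrum, "gc_spectrum"))
  tot <- colSums(unclass(spectrum))
  edges <- attr(spectrum, "bin_edges")
  i <- which.max(tot)
  (edges[i] + edges[i + 1]) / 2
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("gc_spectrum: %d sequences in %d strata, bin width %g%%, mode %.1f%%\n",
              sum(x), nrow(x), attr(x, "bin_width"), spectrum_mode(x)))
  invisible(x)
}
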