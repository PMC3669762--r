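## seqio: FASTA and table I/O, scaffold collections, network export.

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "-")

#' Construct a scaffold collection
#'
#' A `scaffold_set` couples a [Biostrings::DNAStringSet] of assembled
#' scaffold sequences with a per-scaffold metadata table (site of origin,
#' optional taxon label, optional depth of coverage).
#'
#' @param sequences named character vector or `DNAStringSet`; names are
#'   scaffold ids (unique, non-empty). Sequences are folded to uppercase.
#' @param site character vector of site labels (recycled), or `NA`.
#' @param taxon optional character vector of taxon labels, or `NA`.
#' @param coverage optional numeric vector of fold coverage (>= 0), or `NA`.
#' @return An object of class `scaffold_set` with elements `seq`
#'   (`DNAStringSet`) and `meta` (data.frame with columns `id`, `site`,
#'   `taxon`, `coverage`).
#' @export
#' @examples
#' s <- scaffold_set(c(s1 = "ACGT", s2 = "GGCC"), site = "siteA")
#' length(s)
scaffold_set <- function(sequences, site = NA_character_,
                         taxon = NA_character_, coverage = NA_real_) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  ids <- names(sequences)
  n <- length(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every scaffold must have a non-empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate scaffold id(s): ", paste(head(dup, 5), collapse = ", "))
  if (any(Biostrings::width(sequences) < 1))
    stop("zero-length sequence not allowed")
  cov <- rep_len(as.numeric(coverage), n)
  if (any(!is.na(cov) & cov < 0)) stop("coverage must be >= 0")
  meta <- data.frame(
    id = ids,
    site = rep_len(as.character(site), n),
    taxon = rep_len(as.character(taxon), n),
    coverage = cov,
    stringsAsFactors = FALSE
  )
  structure(list(seq = sequences, meta = meta), class = "scaffold_set")
}

#' @export
length.scaffold_set <- function(x) length(x$seq)

#' @export
`[.scaffold_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$meta$id)
  structure(list(seq = x$seq[i], meta = x$meta[i, , drop = FALSE]),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  w <- Biostrings::width(x$seq)
  cat(sprintf("scaffold_set: %d scaffolds, %.2f Mb total, lengths %d-%d bp\n",
              length(w), sum(w) / 1e6,
              if (length(w)) min(w) else 0L, if (length(w)) max(w) else 0L))
  ns <- unique(x$meta$site)
  cat("  sites:", paste(head(ns, 8), collapse = ", "),
      if (length(ns) > 8) "..." else "", "\n")
  invisible(x)
}

#' Scaffold lengths in bases
#' @param x a `scaffold_set`.
#' @return Named integer vector of sequence lengths.
#' @export
scaffold_lengths <- function(x) {
  stopifnot(inherits(x, "scaffold_set"))
  setNames(Biostrings::width(x$seq), x$meta$id)
}

#' Read scaffolds from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; sequences are
#' folded to uppercase. Duplicate ids and non-IUPAC characters are errors.
#'
#' @param path FASTA file path.
#' @param site optional site label applied to every record.
#' @return A [scaffold_set].
#' @export
read_fasta <- function(path, site = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) {
        .fasta_diagnose(path)
        stop("failed to parse FASTA '", path, "': ", conditionMessage(e))
      }
    ),
    warning = function(w) {
      # Biostrings silently drops invalid codes; surface them with position
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        .fasta_diagnose(path)
      invokeRestart("muffleWarning")
    }
  )
  if (!length(seqs)) stop("no records in FASTA file: ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, "", 1L)
  scaffold_set(seqs, site = site)
}

## Locate the first offending character so parse errors are actionable.
.fasta_diagnose <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    ok <- strsplit(toupper(ln), "")[[1]] %in% IUPAC_DNA
    if (any(!ok)) {
      stop(sprintf("non-IUPAC character '%s' at line %d, column %d of %s",
                   substr(ln, which(!ok)[1], which(!ok)[1]), i, which(!ok)[1],
                   path))
    }
  }
  invisible(NULL)
}

#' Write scaffolds to a FASTA file
#' @param x a `scaffold_set`.
#' @param path output path.
#' @param width line width for wrapped sequence.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "scaffold_set"))
  Biostrings::writeXStringSet(x$seq, path, width = width)
  invisible(path)
}

#' Read a scaffold annotation table
#'
#' Tab-delimited UTF-8 with a header row; lines starting with `#` are
#' ignored. Column `id` is mandatory; `site`, `taxon` and `coverage` are
#' optional and stay absent (not defaulted) when missing from the file.
#'
#' @param path file path.
#' @return A data.frame of class `annotation_table`, keyed by unique `id`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(tab))
    stop("annotation table lacks mandatory column 'id'; found: ",
         paste(names(tab), collapse = ", "))
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicated scaffold id(s) in annotation: ",
         paste(head(dup, 5), collapse = ", "))
  if ("coverage" %in% names(tab)) {
    tab$coverage <- as.numeric(tab$coverage)
    if (any(!is.na(tab$coverage) & tab$coverage < 0))
      stop("negative coverage in annotation table")
  }
  class(tab) <- c("annotation_table", "data.frame")
  tab
}

#' Join an annotation table onto a scaffold collection
#'
#' Unmatched ids (on either side) are reported via attributes rather than
#' silently dropped.
#'
#' @param x a `scaffold_set`.
#' @param annot an `annotation_table` (or data.frame with an `id` column).
#' @return `x` with updated metadata; attributes `unmatched_scaffolds` and
#'   `unmatched_annotations` list ids without a partner.
#' @export
annotate_scaffolds <- function(x, annot) {
  stopifnot(inherits(x, "scaffold_set"), "id" %in% names(annot))
  m <- match(x$meta$id, annot$id)
  for (col in intersect(c("site", "taxon", "coverage"), names(annot))) {
    hit <- !is.na(m)
    x$meta[[col]][hit] <- annot[[col]][m[hit]]
  }
  attr(x, "unmatched_scaffolds") <- x$meta$id[is.na(m)]
  attr(x, "unmatched_annotations") <- setdiff(annot$id, x$meta$id)
  x
}

#' Write a data frame as a tab-delimited table
#' @param rows data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a support network to SIF or GraphML
#'
#' Edges carry a co-clustering support weight in `[0, 1]`. The SIF dialect is
#' `a pp b`, one edge per line (weights are not representable in SIF);
#' GraphML stores the weight as numeric edge attribute `support`.
#'
#' @param edges data.frame with columns `from`, `to`, `support`.
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(all(c("from", "to", "support") %in% names(edges)))
  if (nrow(edges) && (any(edges$support < 0) || any(edges$support > 1)))
    stop("support weights must lie in [0, 1]")
  if (format == "sif") {
    writeLines(if (nrow(edges)) paste(edges$from, "pp", edges$to)
               else character(0), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "support"), drop = FALSE], directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_graph_file()]
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @return data.frame with columns `from`, `to` and, for GraphML, `support`.
#' @export
read_graph_file <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(data.frame(from = character(0), to = character(0)))
    parts <- strsplit(lines, "[ \t]+")
    data.frame(from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 3L),
               stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    df <- df[, intersect(c("from", "to", "support"), names(df)), drop = FALSE]
    rownames(df) <- NULL
    df
  }
}
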