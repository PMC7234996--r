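.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.SUBJECT_ALPHABET <- c("A", "C", "G", "T", "N")

#' Compile an IUPAC degenerate pattern
#'
#' Parses a pattern over the 15 IUPAC nucleotide codes into per-position
#' allowed-base sets and computes its degeneracy (the number of exact
#' sequences it expands to).  The antioxidant response element consensus
#' `TGASWMAKCN` has degeneracy 64.
#'
#' @param text pattern string (case-insensitive).
#' @return An object of class `"iupac_pattern"`: list with `pattern`,
#'   `length`, `sets` (list of character vectors), `degeneracy`.
#' @examples
#' compile_pattern("TGASWMAKCN")$degeneracy   # 64
#' @export
compile_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    .fail("pattern must be a non-empty string")
  chars <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC))
  if (length(bad))
    .fail("invalid IUPAC symbol '", chars[bad[1L]], "' at position ",
          bad[1L])
  sets <- .IUPAC[chars]
  out <- list(pattern = paste(chars, collapse = ""), length = length(chars),
              sets = sets, degeneracy = prod(lengths(sets)))
  class(out) <- "iupac_pattern"
  out
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat("IUPAC pattern", x$pattern, "(length", x$length, ", degeneracy",
      paste0(x$degeneracy, ")"), "\n")
  invisible(x)
}

#' The ARE consensus pattern
#'
#' The de novo human antioxidant-response-element consensus `TGASWMAKCN`
#' (S = G/C, W = A/T, M = A/C, K = G/T, N = any), the NRF2 binding motif
#' searched upstream of target genes.
#'
#' @return A compiled `"iupac_pattern"`.
#' @export
are_consensus <- function() compile_pattern("TGASWMAKCN")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over `A/C/G/T/N` (case preserved as upper).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(x) {
  chars <- rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", x), "",
                        fixed = TRUE)[[1L]])
  paste(chars, collapse = "")
}

# allowed[subject_base_index, pattern_position]; subject 'N' (unknown base)
# matches only pattern 'N' -- an unknown base can only satisfy a position
# that accepts everything.
.pattern_matrix <- function(pattern) {
  m <- vapply(pattern$sets, function(s) .SUBJECT_ALPHABET %in% s,
              logical(5L))
  m[5L, ] <- vapply(pattern$sets, function(s) length(s) == 4L, NA)
  m
}

#' Scan a sequence for degenerate-pattern matches
#'
#' Reports every offset (0-based, forward-strand coordinates, half-open
#' intervals) at which each sequence base is in the pattern's allowed set;
#' overlapping hits are all reported.  With `strands = "both"` the reverse
#' complement is also scanned and its hits are reported in forward-strand
#' coordinates with strand `"-"`; `matched_text` is always the
#' forward-strand slice.  An unknown base `N` in the sequence matches only
#' pattern positions that accept any base.
#'
#' @param sequence character scalar over `A/C/G/T/N` (case-folded).
#' @param pattern an `"iupac_pattern"` or pattern string.
#' @param strands `"both"` (default) or `"forward"`.
#' @param sequence_id identifier copied into the result.
#' @return data.frame with columns `sequence_id`, `start`, `end`, `strand`,
#'   `matched_text`, sorted by `start` then strand.  Empty (zero rows) when
#'   the sequence is shorter than the pattern.
#' @examples
#' scan_motif("TGACTCAGCA", are_consensus(), strands = "forward")
#' @export
scan_motif <- function(sequence, pattern = are_consensus(),
                       strands = c("both", "forward"),
                       sequence_id = NA_character_) {
  strands <- match.arg(strands)
  if (inherits(pattern, "character")) pattern <- compile_pattern(pattern)
  if (!inherits(pattern, "iupac_pattern")) .fail("invalid pattern")
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(chars, .SUBJECT_ALPHABET)
  if (anyNA(idx))
    .fail("sequence contains non-ACGTN character(s): ",
          paste(unique(chars[is.na(idx)]), collapse = ", "))
  m <- pattern$length
  L <- length(chars)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched_text = character(), stringsAsFactors = FALSE)
  if (L < m) return(empty)
  allow <- .pattern_matrix(pattern)

  starts_on <- function(ix) {
    ok <- rep(TRUE, L - m + 1L)
    for (j in seq_len(m))
      ok <- ok & allow[, j][ix[j:(L - m + j)]]
    which(ok) - 1L                       # 0-based
  }

  fwd <- starts_on(idx)
  hits <- if (length(fwd))
    data.frame(sequence_id = sequence_id, start = fwd, end = fwd + m,
               strand = "+", stringsAsFactors = FALSE) else empty[1:4]
  if (strands == "both") {
    rc_idx <- rev(c(4L, 3L, 2L, 1L, 5L)[idx])   # complement then reverse
    rv <- starts_on(rc_idx)
    if (length(rv)) {
      fstart <- L - rv - m
      hits <- rbind(hits,
                    data.frame(sequence_id = sequence_id, start = fstart,
                               end = fstart + m, strand = "-",
                               stringsAsFactors = FALSE))
    }
  }
  if (!nrow(hits)) return(empty)
  hits$matched_text <- substring(s, hits$start + 1L, hits$end)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract the upstream promoter window of a locus
#'
#' For a plus-strand locus `[s, e)` the window is
#' `[max(0, s - window), s)` and the sequence is taken as-is; for a
#' minus-strand locus it is `[e, min(L, e + window))` reverse-complemented,
#' so the returned sequence always reads 5' to 3' relative to the gene.
#' Windows truncated at contig edges are extracted (not discarded) and the
#' truncation is recorded.
#'
#' @param sequence character scalar (the contig, forward strand).
#' @param locus list or one-row data.frame with `locus_id`, `sequence_id`,
#'   `start`, `end` (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @param window window size in bp upstream of the locus start (default
#'   1000, i.e. ~1 kb upstream).
#' @return An object of class `"upstream_window"`: list with `locus_id`,
#'   `sequence_id`, `start`, `end` (forward-strand interval of the window),
#'   `strand`, `seq`, `length`, `truncated`.
#' @export
extract_upstream <- function(sequence, locus, window = 1000L) {
  L <- nchar(sequence)
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  strand <- as.character(locus$strand)
  if (is.na(s) || is.na(e) || s < 0L || e > L || s >= e)
    .fail("locus [", locus$start, ",", locus$end,
          ") outside sequence of length ", L)
  if (!strand %in% c("+", "-")) .fail("locus strand must be '+' or '-'")
  if (strand == "+") {
    ws <- max(0L, s - as.integer(window)); we <- s
    seq <- substring(sequence, ws + 1L, we)
  } else {
    ws <- e; we <- min(L, e + as.integer(window))
    seq <- reverse_complement(substring(sequence, ws + 1L, we))
  }
  out <- list(locus_id = locus$locus_id, sequence_id = locus$sequence_id,
              start = ws, end = we, strand = strand, seq = toupper(seq),
              length = we - ws, truncated = (we - ws) < window)
  class(out) <- "upstream_window"
  out
}

#' Count AREs in the upstream windows of gene loci
#'
#' For every locus, extracts the upstream window ([extract_upstream()]) and
#' scans it ([scan_motif()], both strands by default); hits are mapped back
#' to forward-strand coordinates on the source sequence.  Loci with zero
#' hits are retained with `n_hits = 0` -- the absence of an ARE is itself a
#' finding.  Loci sharing sequence are scanned independently.
#'
#' @param sequences named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param loci data.frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open), `locus_id`, `strand`, or a path to a BED file
#'   (read with [read_loci_bed()]).
#' @param pattern an `"iupac_pattern"` (default the ARE consensus).
#' @param window upstream window size in bp (default 1000).
#' @param strands `"both"` (default) or `"forward"`.
#' @return list with `counts` (data.frame `locus_id`, `sequence_id`,
#'   `n_hits`) and `hits` (data.frame `locus_id`, `sequence_id`, `start`,
#'   `end`, `strand`, `matched_text`, forward-strand 0-based half-open
#'   coordinates on the source sequence).
#' @export
count_ares <- function(sequences, loci, pattern = are_consensus(),
                       window = 1000L, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    .fail("sequences must be named")
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  if (is.character(loci) && length(loci) == 1L)
    loci <- read_loci_bed(loci)
  missing <- setdiff(unique(loci$sequence_id), names(sequences))
  if (length(missing))
    .fail("sequence_id(s) absent from FASTA: ",
          paste(missing, collapse = ", "))

  hit_list <- vector("list", nrow(loci))
  counts <- data.frame(locus_id = loci$locus_id,
                       sequence_id = loci$sequence_id,
                       n_hits = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, , drop = FALSE]
    win <- extract_upstream(sequences[[lc$sequence_id]], lc, window)
    h <- scan_motif(win$seq, pattern, strands, sequence_id = lc$sequence_id)
    if (nrow(h)) {
      if (win$strand == "+") {
        h$start <- win$start + h$start
      } else {
        # window seq is the reverse complement of forward [start, end)
        local_start <- h$start
        h$start <- win$start + (win$length - local_start - pattern$length)
        h$strand <- ifelse(h$strand == "+", "-", "+")
      }
      h$end <- h$start + pattern$length
      h$matched_text <- substring(sequences[[lc$sequence_id]],
                                  h$start + 1L, h$end)
      h <- cbind(locus_id = lc$locus_id, h, stringsAsFactors = FALSE)
      h <- h[order(h$start, h$strand), , drop = FALSE]
      counts$n_hits[i] <- nrow(h)
      hit_list[[i]] <- h
    }
  }
  hits <- do.call(rbind, hit_list)
  if (is.null(hits))
    hits <- data.frame(locus_id = character(), sequence_id = character(),
                       start = integer(), end = integer(),
                       strand = character(), matched_text = character(),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(counts = counts, hits = hits)
}

#' Read gene loci from a BED file
#'
#' BED is 0-based half-open; the returned data.frame keeps that convention
#' (`start`, `end`).  Records without a strand are treated as plus-strand.
#'
#' @param path BED file path.
#' @return data.frame with `sequence_id`, `start`, `end`, `locus_id`,
#'   `strand`.
#' @export
read_loci_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("locus", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(sequence_id = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             locus_id = nm, strand = strand, stringsAsFactors = FALSE)
}
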