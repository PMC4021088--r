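# Verification metrics for designed sequences.

#' G+C content of a sequence
#'
#' @param seq DNA string, length >= 1.
#' @return Percentage `100 * (#G + #C) / length`, rounded to one decimal.
#' @examples
#' gc_content("GCGC")
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  round(100 * (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq), 1)
}

#' Position-wise nucleotide identity of two equal-length sequences
#'
#' The natural identity metric for a synonymous recoding, which preserves
#' length: matches are counted column by column with no gaps.
#'
#' @param a,b DNA strings of equal length (case-insensitive).
#' @return An `identity_report`: list with `percent_identity` (one
#'   decimal), `aligned_length`, `matches`, `mode = "positional"`.
#' @examples
#' positional_identity("AAA", "AAG")$percent_identity
#' @export
positional_identity <- function(a, b) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop("length mismatch (", nchar(a), " vs ", nchar(b),
         "): use global_identity() for unequal lengths", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- sum(ca == cb)
  structure(list(percent_identity = round(100 * m / length(ca), 1),
                 aligned_length = length(ca), matches = m,
                 mode = "positional"),
            class = "identity_report")
}

#' Global-alignment nucleotide identity
#'
#' Needleman-Wunsch global alignment (linear gap penalty) as the fallback
#' for unequal-length pairs; identity is matches over alignment columns.
#'
#' @param a,b Non-empty DNA strings.
#' @param match,mismatch,gap Alignment scores (defaults 1, -1, -2).
#' @return An `identity_report` with `mode = "global_alignment"`.
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(pa)
  m <- sum(pa == sa & pa != "-")
  structure(list(percent_identity = round(100 * m / cols, 1),
                 aligned_length = cols, matches = m,
                 mode = "global_alignment"),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("%s identity: %.1f%% (%d/%d columns)\n",
              x$mode, x$percent_identity, x$matches, x$aligned_length))
  invisible(x)
}

#' Summarise codon and base changes between a native CDS and its recoding
#'
#' Both sequences must be the same length and encode the same protein
#' (the recoding is synonymous by construction).  Counts how many codons
#' were altered and how many bases changed at each codon position; for a
#' synonymous recoding third-position changes dominate.
#'
#' @param native_cds,synthetic_cds Equal-length synonymous CDS strings.
#' @return List with `codons_total`, `codons_changed`,
#'   `per_position_base_changes` (named vector, positions 1-3).
#' @export
codon_change_summary <- function(native_cds, synthetic_cds) {
  a <- check_dna(native_cds, "native_cds")
  b <- check_dna(synthetic_cds, "synthetic_cds")
  if (nchar(a) != nchar(b)) {
    stop("length mismatch: a synonymous recoding preserves length",
         call. = FALSE)
  }
  pa <- translate_cds(a); pb <- translate_cds(b)
  if (as.character(pa) != as.character(pb)) {
    stop("protein mismatch: the synthetic sequence must be synonymous",
         call. = FALSE)
  }
  ca <- split_codons(a); cb <- split_codons(b)
  changed <- ca != cb
  ch_a <- strsplit(a, "", fixed = TRUE)[[1]]
  ch_b <- strsplit(b, "", fixed = TRUE)[[1]]
  pos <- rep_len(1:3, length(ch_a))
  diffs <- ch_a != ch_b
  per_pos <- vapply(1:3, function(p) sum(diffs[pos == p]), integer(1))
  list(codons_total = length(ca),
       codons_changed = sum(changed),
       per_position_base_changes = stats::setNames(per_pos,
                                                   c("pos1", "pos2", "pos3")))
}

#' Verify the published design numbers for a native/synthetic pair
#'
#' Computes the report one would use to check a deposited synthetic gene
#' against its native counterpart: GC content of both, position-wise
#' nucleotide identity, and the codon-change summary.  Sequences must be
#' supplied by the caller (e.g. downloaded from GenBank); none are shipped
#' with the package.
#'
#' @param native,synthetic Equal-length CDS strings.
#' @return List with `gc_native`, `gc_synthetic`, `percent_identity`,
#'   `codon_changes`.
#' @export
verify_published_designs <- function(native, synthetic) {
  list(gc_native = gc_content(native),
       gc_synthetic = gc_content(synthetic),
       percent_identity = positional_identity(native,
                                              synthetic)$percent_identity,
       codon_changes = codon_change_summary(native, synthetic))
}
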