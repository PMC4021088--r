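# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' @param seq A single DNA string over A/C/G/T.
#' @return The reverse complement as an uppercase character string.
#' @examples
#' reverse_complement("GATC")
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# Vectorised reverse complement on a character vector (no validation).
revcomp_vec <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

check_dna <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(sprintf("`%s` must be a single character string", arg),
         call. = FALSE)
  }
  if (nzchar(gsub("[ACGT]", "", toupper(seq)))) {
    bad <- unique(strsplit(gsub("[ACGT]", "", toupper(seq)), "",
                           fixed = TRUE)[[1]])
    stop(sprintf("invalid alphabet: `%s` contains non-ACGT character(s): %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(toupper(seq))
}

check_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", arg), call. = FALSE)
  }
  invisible(x)
}

# Split a CDS into its codons.
split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# G+C count of each codon in a character vector.
codon_gc <- function(codons) {
  nchar(codons) - nchar(gsub("[GC]", "", codons))
}

# Empty violation table with the canonical columns.
empty_violations <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             partner_start = integer(0), partner_end = integer(0),
             matched = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

# Assemble a violation table row-set; partner columns NA unless two-armed.
make_violations <- function(kind, start, end, matched, label,
                            partner_start = NA_integer_,
                            partner_end = NA_integer_) {
  if (length(start) == 0L) return(empty_violations())
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             partner_start = as.integer(partner_start),
             partner_end = as.integer(partner_end),
             matched = matched, label = label, stringsAsFactors = FALSE)
}

sort_violations <- function(v) {
  if (nrow(v) == 0L) return(v)
  v <- v[order(v$start, v$kind, v$end), , drop = FALSE]
  rownames(v) <- NULL
  v
}
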