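# Feature scanners.  Every scanner reports 1-based closed intervals on the
# forward strand and satisfies substr(seq, start, end) == matched.

#' Scan for degenerate IUPAC motifs
#'
#' Reports every occurrence (including overlapping occurrences) of each
#' pattern, IUPAC codes expanded per standard degeneracy.  With
#' `both_strands = TRUE` the reverse strand is also scanned and hits are
#' reported in forward-strand coordinates.
#'
#' @param seq DNA string (ACGT).
#' @param patterns Motif data frame (`label`, `category`, `pattern`).
#' @param both_strands Scan the reverse strand too?
#' @return Violation data frame (`kind`, `start`, `end`, `partner_start`,
#'   `partner_end`, `matched`, `label`), sorted by start.
#' @export
scan_motifs <- function(seq, patterns, both_strands = FALSE) {
  seq <- check_dna(seq)
  subject <- Biostrings::DNAString(seq)
  out <- empty_violations()
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[i]
    bad <- setdiff(strsplit(pat, "", fixed = TRUE)[[1]], names(IUPAC_SETS))
    if (length(bad) > 0L) {
      stop(sprintf("pattern-compile error in '%s': invalid IUPAC code(s) %s",
                   pat, paste(unique(bad), collapse = ", ")),
           call. = FALSE)
    }
    kind <- if (identical(patterns$category[i], "restriction_site")) {
      "restriction_site"
    } else "motif"
    pats <- Biostrings::DNAString(pat)
    hits <- Biostrings::matchPattern(pats, subject, fixed = "subject")
    if (length(hits) > 0L) {
      out <- rbind(out, make_violations(
        kind, BiocGenerics::start(hits), BiocGenerics::end(hits),
        substring(seq, BiocGenerics::start(hits),
                  BiocGenerics::end(hits)),
        patterns$label[i]))
    }
    if (both_strands) {
      rc <- Biostrings::reverseComplement(pats)
      if (as.character(rc) != pat) {
        hits <- Biostrings::matchPattern(rc, subject, fixed = "subject")
        if (length(hits) > 0L) {
          out <- rbind(out, make_violations(
            kind, BiocGenerics::start(hits), BiocGenerics::end(hits),
            substring(seq, BiocGenerics::start(hits),
                      BiocGenerics::end(hits)),
            paste0(patterns$label[i], "_rc")))
        }
      }
    }
  }
  sort_violations(out)
}

#' Find maximal A/T-only runs
#'
#' A run is any stretch consisting only of A and/or T (mixed allowed).
#' Only maximal runs — not extendable in either direction — of length at
#' least `min_run` are reported.
#'
#' @param seq DNA string.
#' @param min_run Minimum run length (>= 2).
#' @return Violation data frame with kind `"at_run"`.
#' @export
find_at_runs <- function(seq, min_run = 6L) {
  seq <- check_dna(seq)
  if (min_run < 2L) stop("min_run must be >= 2", call. = FALSE)
  m <- gregexpr(sprintf("[AT]{%d,}", min_run), seq)[[1]]
  if (m[1] == -1L) return(empty_violations())
  len <- attr(m, "match.length")
  sort_violations(make_violations(
    "at_run", as.integer(m), as.integer(m) + len - 1L,
    substring(seq, m, m + len - 1L), "at_run"))
}

#' Find maximal direct repeat pairs
#'
#' Reports every pair of identical non-overlapping substrings of length at
#' least `min_len`, as maximal matches (extended left then right as far as
#' the copies agree without letting the arms collide).  The first copy is
#' `[start, end]`, the second `[partner_start, partner_end]`.
#'
#' @param seq DNA string.
#' @param min_len Minimum repeat arm length (>= 4).
#' @return Violation data frame with kind `"direct_repeat"`.
#' @export
find_direct_repeats <- function(seq, min_len = 10L) {
  seq <- check_dna(seq)
  if (min_len < 4L) stop("min_len must be >= 4", call. = FALSE)
  n <- nchar(seq)
  L <- as.integer(min_len)
  if (n < 2L * L) return(empty_violations())
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  w <- substring(seq, 1:(n - L + 1L), L:n)
  groups <- split(seq_along(w), w)
  groups <- groups[lengths(groups) > 1L]
  seen <- character(0)
  rows <- list()
  for (g in groups) {
    for (a in seq_len(length(g) - 1L)) {
      for (b in (a + 1L):length(g)) {
        i <- g[a]; j <- g[b]
        if (j - i < L) next  # seed copies overlap
        s1 <- i; e1 <- i + L - 1L; s2 <- j; e2 <- j + L - 1L
        while (s1 > 1L && s2 - 1L > e1 && ch[s1 - 1L] == ch[s2 - 1L]) {
          s1 <- s1 - 1L; s2 <- s2 - 1L
        }
        while (e2 < n && e1 + 1L < s2 && ch[e1 + 1L] == ch[e2 + 1L]) {
          e1 <- e1 + 1L; e2 <- e2 + 1L
        }
        key <- paste(s1, e1, s2, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- make_violations(
          "direct_repeat", s1, e1, substring(seq, s1, e1),
          "direct_repeat", s2, e2)
      }
    }
  }
  if (length(rows) == 0L) return(empty_violations())
  sort_violations(do.call(rbind, rows))
}

#' Find maximal inverted repeats (hairpin stems)
#'
#' Reports every pair of non-overlapping substrings where the second arm
#' equals the reverse complement of the first and both arms are at least
#' `min_stem` long; the transcribed copy of such a pair can fold into a
#' double-stranded stem.  Loop length (gap between the arms) is
#' unconstrained, including zero.  Arms are extended maximally both outward
#' and into the loop.
#'
#' @param seq DNA string.
#' @param min_stem Minimum arm length (>= 2).
#' @return Violation data frame with kind `"inverted_repeat"`; the 5' arm
#'   is `[start, end]`, the 3' arm `[partner_start, partner_end]`.
#' @export
find_inverted_repeats <- function(seq, min_stem = 12L) {
  seq <- check_dna(seq)
  if (min_stem < 2L) stop("min_stem must be >= 2", call. = FALSE)
  n <- nchar(seq)
  L <- as.integer(min_stem)
  if (n < 2L * L) return(empty_violations())
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  co <- unname(COMPLEMENT[ch])  # complement of each base, same order
  w <- substring(seq, 1:(n - L + 1L), L:n)
  r <- paste(rev(co), collapse = "")  # reverse complement of seq
  starts <- 1:(n - L + 1L)
  # reverse complement of the L-mer at position k, via the revcomp string
  rcw <- substring(r, n - starts - L + 2L, n - starts + 1L)
  by_kmer <- split(starts, w)
  seen <- character(0)
  rows <- list()
  for (i in starts) {
    js <- by_kmer[[rcw[i]]]
    if (is.null(js)) next
    for (j in js[js >= i + L]) {
      s1 <- i; e1 <- i + L - 1L; s2 <- j; e2 <- j + L - 1L
      while (s1 > 1L && e2 < n && ch[s1 - 1L] == co[e2 + 1L]) {
        s1 <- s1 - 1L; e2 <- e2 + 1L
      }
      while (e1 + 1L < s2 - 1L && ch[e1 + 1L] == co[s2 - 1L]) {
        e1 <- e1 + 1L; s2 <- s2 - 1L
      }
      key <- paste(s1, e1, s2, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- make_violations(
        "inverted_repeat", s1, e1, substring(seq, s1, e1),
        "inverted_repeat", s2, e2)
    }
  }
  if (length(rows) == 0L) return(empty_violations())
  sort_violations(do.call(rbind, rows))
}

#' Find maximal DNA palindromes
#'
#' A DNA palindrome is an even-length substring equal to its own reverse
#' complement (e.g. the EcoRI site GAATTC).  Maximal palindromes of length
#' at least `min_len` are reported once per centre.
#'
#' @param seq DNA string.
#' @param min_len Minimum palindrome length; must be even and >= 4.
#' @return Violation data frame with kind `"palindrome"`.
#' @export
find_palindromes <- function(seq, min_len = 8L) {
  seq <- check_dna(seq)
  if (min_len %% 2L != 0L) {
    stop("invalid parameter: min_len must be even", call. = FALSE)
  }
  if (min_len < 4L) stop("min_len must be >= 4", call. = FALSE)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  co <- unname(COMPLEMENT[ch])
  rows <- list()
  for (c0 in seq_len(n - 1L)) {  # centre between positions c0 and c0+1
    k <- 0L
    while (c0 - k >= 1L && c0 + 1L + k <= n &&
           ch[c0 - k] == co[c0 + 1L + k]) {
      k <- k + 1L
    }
    if (2L * k >= min_len) {
      s <- c0 - k + 1L; e <- c0 + k
      rows[[length(rows) + 1L]] <- make_violations(
        "palindrome", s, e, substring(seq, s, e), "palindrome")
    }
  }
  if (length(rows) == 0L) return(empty_violations())
  sort_violations(do.call(rbind, rows))
}

#' Screen a sequence against a full constraint set
#'
#' Runs every finder (motifs, restriction sites, A/T runs, direct repeats,
#' inverted repeats, palindromes) and checks the G+C content against the
#' target window.  A GC breach is reported as a `gc_window` violation
#' spanning the whole sequence (`matched` is `NA` for this kind).
#'
#' @param seq DNA string.
#' @param constraints A [design_constraints()] object.
#' @return A `screen_report`: list with `violations` (sorted data frame),
#'   `gc_percent`, `gc_ok`, `counts` (violations per kind) and
#'   `seq_length`.
#' @export
screen <- function(seq, constraints = design_constraints()) {
  seq <- check_dna(seq)
  stopifnot(inherits(constraints, "design_constraints"))
  v <- rbind(
    scan_motifs(seq, constraints$motifs, constraints$scan_both_strands),
    scan_motifs(seq, constraints$forbidden_sites),
    find_at_runs(seq, constraints$min_at_run),
    find_direct_repeats(seq, constraints$min_direct_repeat),
    find_inverted_repeats(seq, constraints$min_stem),
    find_palindromes(seq, constraints$min_palindrome)
  )
  gc <- gc_content(seq)
  gc_ok <- abs(gc - constraints$gc_target) <= constraints$gc_window
  if (!gc_ok) {
    v <- rbind(v, make_violations("gc_window", 1L, nchar(seq),
                                  NA_character_, "gc_window"))
  }
  v <- sort_violations(v)
  counts <- table(factor(v$kind,
                         levels = c("motif", "restriction_site", "at_run",
                                    "direct_repeat", "inverted_repeat",
                                    "palindrome", "gc_window")))
  structure(list(violations = v, gc_percent = gc, gc_ok = gc_ok,
                 counts = counts, seq_length = nchar(seq)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report: ", nrow(x$violations), " violation(s) in ",
      x$seq_length, " nt; GC ", x$gc_percent, "% (",
      if (x$gc_ok) "in window" else "out of window", ")\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0) {
    cat(paste0("  ", names(nz), ": ", nz, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a violation report as tab-delimited text
#'
#' @param report A `screen_report` or a violation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_violations <- function(report, path) {
  v <- if (inherits(report, "screen_report")) report$violations else report
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
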