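#' Create a degenerate motif pattern
#'
#' @param pattern IUPAC degenerate DNA string (length >= 4).
#' @param label Short name for reports.
#' @param category One of `"polyadenylation"`, `"splice_signal"`,
#'   `"rna_instability"`, `"restriction_site"`, `"user"`.
#' @return A one-row `data.frame` with columns `label`, `category`,
#'   `pattern`; rows of several calls can be `rbind`-ed into a motif set.
#' @export
motif_pattern <- function(pattern, label,
                          category = c("user", "polyadenylation",
                                       "splice_signal", "rna_instability",
                                       "restriction_site")) {
  category <- match.arg(category)
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "", fixed = TRUE)[[1]],
                 names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf("pattern-compile error in '%s': invalid IUPAC code(s) %s",
                 pattern, paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  }
  if (nchar(pattern) < 4L) {
    stop(sprintf("pattern '%s' shorter than 4 nt", pattern), call. = FALSE)
  }
  data.frame(label = label, category = category, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Default excluded-motif set
#'
#' The shipped defaults cover the classes of signals screened out when the
#' luciferase reporters were recoded for a monocot host: canonical and
#' near-canonical plant polyadenylation signals, the AU-rich RNA
#' instability element, and plant intron splice donor/acceptor consensus
#' sites.  The set is a starting point, fully replaceable via
#' [read_motif_set()] or a user-built data frame.
#'
#' @return Data frame with columns `label`, `category`, `pattern`.
#' @export
default_motif_set <- function() {
  rbind(
    motif_pattern("AATAAA", "polyA_canonical", "polyadenylation"),
    motif_pattern("AATAAT", "polyA_variant",   "polyadenylation"),
    motif_pattern("AATTAAA", "polyA_extended", "polyadenylation"),
    motif_pattern("ATTTA",  "ARE_instability", "rna_instability"),
    motif_pattern("GGTAAGT", "splice_donor",   "splice_signal"),
    motif_pattern("TTTTCAG", "splice_acceptor", "splice_signal")
  )
}

# Default cloning-site patterns (NotI / PacI); both are their own reverse
# complements, so strand is moot.
default_forbidden_sites <- function() {
  rbind(
    motif_pattern("GCGGCCGC", "NotI", "restriction_site"),
    motif_pattern("TTAATTAA", "PacI", "restriction_site")
  )
}

#' Read / write motif sets as tab-delimited files
#'
#' Files have a header and columns `label`, `category`, `pattern`.
#'
#' @param path File path.
#' @param motifs Motif data frame (as from [default_motif_set()]).
#' @return `read_motif_set()` returns the validated motif data frame;
#'   `write_motif_set()` returns `path` invisibly.
#' @export
read_motif_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    motif_pattern(df$pattern[i], df$label[i], df$category[i])
  }))
}

#' @rdname read_motif_set
#' @export
write_motif_set <- function(motifs, path) {
  utils::write.table(motifs[, c("label", "category", "pattern")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Design constraints for sequence screening and repair
#'
#' Bundles every exclusion rule applied to candidate coding sequences.
#' Defaults follow the recoding strategy used for the sugarcane-optimised
#' luciferases: hairpin stems of 12 bp or more are disallowed, candidate GC
#' content must sit within `gc_window` percentage points of `gc_target`,
#' and the default motif set excludes polyadenylation signals, AU-rich
#' instability elements and splice-site consensus sequences.  Thresholds
#' with no published value (`min_at_run`, `min_direct_repeat`,
#' `min_palindrome`) default to conventional gene-synthesis screening
#' values and are fully configurable.
#'
#' @param motifs Motif data frame (label/category/pattern).
#' @param min_at_run Minimum reportable A/T-only run length (default 6).
#' @param min_direct_repeat Minimum direct-repeat arm length (default 10).
#' @param min_palindrome Minimum palindrome length, even (default 8).
#' @param min_stem Minimum inverted-repeat (hairpin stem) arm length
#'   (default 12).
#' @param forbidden_sites Restriction-site motif data frame (default NotI
#'   `GCGGCCGC` and PacI `TTAATTAA`).
#' @param gc_target Target G+C percentage (default 55, the mean of the
#'   host's coding sequences).
#' @param gc_window Allowed half-width around `gc_target`, percentage
#'   points (default 3).
#' @param scan_both_strands Also scan motifs on the reverse strand?
#' @return A `design_constraints` object (a validated list).
#' @export
design_constraints <- function(motifs = default_motif_set(),
                               min_at_run = 6L,
                               min_direct_repeat = 10L,
                               min_palindrome = 8L,
                               min_stem = 12L,
                               forbidden_sites = default_forbidden_sites(),
                               gc_target = 55,
                               gc_window = 3,
                               scan_both_strands = FALSE) {
  if (min_stem < 2L) stop("min_stem must be >= 2", call. = FALSE)
  if (min_palindrome %% 2L != 0L) {
    stop("invalid parameter: min_palindrome must be even", call. = FALSE)
  }
  if (gc_target <= 0 || gc_target >= 100) {
    stop("gc_target must be strictly between 0 and 100", call. = FALSE)
  }
  structure(list(motifs = motifs,
                 min_at_run = as.integer(min_at_run),
                 min_direct_repeat = as.integer(min_direct_repeat),
                 min_palindrome = as.integer(min_palindrome),
                 min_stem = as.integer(min_stem),
                 forbidden_sites = forbidden_sites,
                 gc_target = gc_target, gc_window = gc_window,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "design_constraints")
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("Design constraints:\n",
      "  motifs: ", nrow(x$motifs), " excluded + ",
      nrow(x$forbidden_sites), " restriction sites\n",
      "  min A/T run ", x$min_at_run,
      ", direct repeat ", x$min_direct_repeat,
      ", palindrome ", x$min_palindrome,
      ", hairpin stem ", x$min_stem, "\n",
      "  GC target ", x$gc_target, " +/- ", x$gc_window, "%\n", sep = "")
  invisible(x)
}
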