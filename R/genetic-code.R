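#' The standard genetic code
#'
#' Returns the standard (NCBI table 1) genetic code as a named character
#' vector mapping each of the 64 uppercase DNA codons to a one-letter amino
#' acid, with `"*"` marking the three stop codons.
#'
#' @return Named character vector of length 64 with attribute `id`.
#' @examples
#' genetic_code()[["ATG"]]
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  structure(as.character(code), names = names(code), id = "standard")
}

# codon -> amino acid lookup, cached at load time in the namespace.
.gc_env <- new.env(parent = emptyenv())

gc_table <- function() {
  if (is.null(.gc_env$code)) {
    .gc_env$code <- genetic_code()
    .gc_env$families <- split(names(.gc_env$code), .gc_env$code)
  }
  .gc_env$code
}

# amino acid -> character vector of synonymous codons ("*" = stops)
codon_families <- function() {
  gc_table()
  .gc_env$families
}

#' Translate a coding sequence
#'
#' Translates an uppercase DNA CDS with the standard genetic code.  Trailing
#' stop codons are stripped from the protein body and reported separately;
#' an internal (premature) stop raises an error.
#'
#' @param cds DNA string, length divisible by 3, alphabet ACGT.
#' @return A character string (one letter per sense codon) with attribute
#'   `n_stops`, the number of trailing stop codons.
#' @examples
#' translate_cds("ATGGCTTAA")
#' @export
translate_cds <- function(cds) {
  cds <- check_dna(cds, "cds")
  if (nchar(cds) %% 3L != 0L) {
    stop("frame error: CDS length ", nchar(cds), " is not divisible by 3",
         call. = FALSE)
  }
  aa <- unname(gc_table()[split_codons(cds)])
  n <- length(aa)
  n_stops <- 0L
  while (n - n_stops >= 1L && aa[n - n_stops] == "*") {
    n_stops <- n_stops + 1L
  }
  body <- aa[seq_len(n - n_stops)]
  if (any(body == "*")) {
    stop("internal stop codon at codon position ",
         which(body == "*")[1], call. = FALSE)
  }
  structure(paste(body, collapse = ""), n_stops = n_stops)
}

#' Build a codon-usage table from coding sequences
#'
#' Tallies every codon of every supplied CDS and computes the relative
#' synonymous frequency of each codon within its amino-acid family, the
#' quantity a host-biased reverse translator samples from.  Untranslatable
#' records (wrong frame, bad alphabet, internal stop) are skipped with a
#' warning and counted in `n_skipped`.  Families with zero total count get
#' uniform frequencies so every protein remains encodable.
#'
#' @param cds_records Character vector (or list) of DNA coding sequences.
#' @param source_label Free-text provenance note stored on the table.
#' @return A `codon_usage_table`: list with `counts` (named integer, all 64
#'   codons), `rel_freq` (named numeric, per-family normalised), `n_cds`,
#'   `n_skipped`, `source_label`.
#' @examples
#' tab <- build_usage_table(c("ATGGCTGCC"))
#' tab$rel_freq[c("GCT", "GCC")]
#' @export
build_usage_table <- function(cds_records, source_label = "user CDS set") {
  cds_records <- unlist(cds_records, use.names = FALSE)
  if (length(cds_records) == 0L) {
    stop("empty input: need at least one coding sequence", call. = FALSE)
  }
  code <- gc_table()
  counts <- stats::setNames(integer(64), names(code))
  n_used <- 0L
  n_skipped <- 0L
  for (rec in cds_records) {
    ok <- tryCatch({ translate_cds(rec); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      n_skipped <- n_skipped + 1L
      warning("skipping untranslatable record", call. = FALSE)
      next
    }
    tab <- table(split_codons(toupper(rec)))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    stop("empty input: no translatable coding sequences", call. = FALSE)
  }
  structure(list(counts = counts,
                 rel_freq = relative_synonymous_freq(counts),
                 n_cds = n_used, n_skipped = n_skipped,
                 source_label = source_label),
            class = "codon_usage_table")
}

# Per-family normalisation of raw codon counts; uniform where a family
# has zero total (keeps sparse training sets usable).
relative_synonymous_freq <- function(counts) {
  rel <- stats::setNames(numeric(length(counts)), names(counts))
  for (fam in codon_families()) {
    tot <- sum(counts[fam])
    rel[fam] <- if (tot > 0) counts[fam] / tot else 1 / length(fam)
  }
  rel
}

#' Parse a Kazusa-style codon-usage table
#'
#' Reads the codon-usage export dialect used by the Kazusa database: fields
#' `codon` `[amino acid]` `frequency-per-thousand` `(count)` or
#' `count`, whitespace-separated, possibly several codons per line.  Counts
#' are taken from the count column; relative synonymous frequencies are
#' recomputed from the counts rather than trusted from the file.
#'
#' @param text Character vector of lines, a single string with newlines, or
#'   a file path (when `is_file = TRUE`).
#' @param is_file Read `text` as a file path?
#' @param source_label Provenance note.
#' @return A `codon_usage_table` (see [build_usage_table()]).
#' @export
parse_kazusa_table <- function(text, is_file = FALSE,
                               source_label = "kazusa") {
  if (is_file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  code <- gc_table()
  counts <- stats::setNames(rep(NA_real_, 64), names(code))
  for (i in seq_along(text)) {
    line <- trimws(text[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    # strip decoration so "GCU A 12.3 (  4503)" and "GCT 4503" both parse
    toks <- strsplit(gsub("[()]", " ", line), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    j <- 1L
    while (j <= length(toks)) {
      codon <- chartr("Uu", "Tt", toupper(toks[[j]]))
      if (!grepl("^[ACGT]{3}$", codon)) {
        stop(sprintf("parse error at line %d: '%s' is not a codon",
                     i, toks[[j]]), call. = FALSE)
      }
      j <- j + 1L
      # optional one-letter amino acid / stop column
      if (j <= length(toks) &&
          grepl("^[A-Za-z*]$", toks[[j]])) j <- j + 1L
      nums <- c()
      while (j <= length(toks) &&
             grepl("^[0-9.]+$", toks[[j]])) {
        nums <- c(nums, as.numeric(toks[[j]]))
        j <- j + 1L
      }
      if (length(nums) == 0L) {
        stop(sprintf("parse error at line %d: no count for codon %s",
                     i, codon), call. = FALSE)
      }
      counts[[codon]] <- nums[[length(nums)]]  # last numeric field = count
    }
  }
  missing <- names(counts)[is.na(counts)]
  if (length(missing) > 0L) {
    stop("incomplete table: missing codon(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  structure(list(counts = counts,
                 rel_freq = relative_synonymous_freq(counts),
                 n_cds = NA_integer_, n_skipped = 0L,
                 source_label = source_label),
            class = "codon_usage_table")
}

#' Drop rare codons and renormalise the sampling distribution
#'
#' A codon is retained iff its relative synonymous frequency is at least
#' `threshold` (default 20%, the cutoff used when the luciferase reporters
#' were recoded for sugarcane).  Surviving frequencies are renormalised to
#' sum to one within each amino-acid family.  If an entire family falls
#' below the threshold the single maximum-frequency codon is kept (ties
#' broken by alphabetical codon order); single-codon amino acids are always
#' retained.
#'
#' @param table A `codon_usage_table`.
#' @param threshold Per-family relative-frequency cutoff in `[0, 1)`.
#' @return An `allowed_codon_set`: list with `allowed` (named list, amino
#'   acid -> named numeric vector of sampling probabilities) and
#'   `threshold_used`.
#' @examples
#' tab <- build_usage_table("ATGGCTGCC")
#' filter_rare_codons(tab, 0.2)$allowed$A
#' @export
filter_rare_codons <- function(table, threshold = 0.20) {
  check_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold >= 1) {
    stop("invalid threshold: must satisfy 0 <= threshold < 1",
         call. = FALSE)
  }
  if (inherits(table, "allowed_codon_set")) {
    fams <- table$allowed
  } else {
    stopifnot(inherits(table, "codon_usage_table"))
    fams <- codon_families()
    fams <- fams[names(fams) != "*"]
    fams <- lapply(fams, function(fam) table$rel_freq[fam])
  }
  allowed <- lapply(fams, function(p) {
    keep <- p >= threshold
    if (!any(keep)) {
      # whole family rare: keep the (alphabetically first) maximum
      ord <- order(-p, names(p))
      keep <- names(p) == names(p)[ord[1]]
    }
    p <- p[keep]
    p / sum(p)
  })
  names(allowed) <- names(fams)
  structure(list(allowed = allowed, threshold_used = threshold),
            class = "allowed_codon_set")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table (", x$source_label, ")\n", sep = "")
  if (!is.na(x$n_cds)) cat("  built from", x$n_cds, "CDS records")
  if (x$n_skipped > 0) cat(" (", x$n_skipped, " skipped)", sep = "")
  cat("\n  total codons counted:", sum(x$counts), "\n")
  invisible(x)
}

#' @export
print.allowed_codon_set <- function(x, ...) {
  n <- vapply(x$allowed, length, integer(1))
  cat("Allowed codon set (threshold ", x$threshold_used, ")\n",
      "  codons retained: ", sum(n), "/61 across ", length(n),
      " amino acids\n", sep = "")
  invisible(x)
}

#' Export a codon-usage table as tab-delimited text
#'
#' @param table A `codon_usage_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- data.frame(codon = names(table$counts),
                   amino_acid = unname(gc_table()[names(table$counts)]),
                   count = unname(table$counts),
                   rel_freq = round(unname(table$rel_freq), 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited codon-usage table written by [write_usage_table()]
#'
#' @param path File path.
#' @return A `codon_usage_table`; frequencies are recomputed from counts.
#' @export
read_usage_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  counts <- stats::setNames(as.integer(df$count), toupper(df$codon))
  missing <- setdiff(names(gc_table()), names(counts))
  if (length(missing) > 0L) {
    stop("incomplete table: missing codon(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- counts[names(gc_table())]
  structure(list(counts = counts,
                 rel_freq = relative_synonymous_freq(counts),
                 n_cds = NA_integer_, n_skipped = 0L,
                 source_label = path),
            class = "codon_usage_table")
}
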