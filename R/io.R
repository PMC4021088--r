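# FASTA and configuration handling.

#' Read a (possibly wrapped) multi-record FASTA file
#'
#' Sequences are uppercased on read (with a message when lowercase input
#' was found); empty files and duplicate record ids are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("note: lowercase residues uppercased on read")
    seqs <- toupper(seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write named sequences as wrapped FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts,
                         pmin(nchar(s), starts + width - 1L)), con)
  }
  invisible(path)
}

config_defaults <- function() {
  list(threshold = 0.20, min_at_run = 6L, min_direct_repeat = 10L,
       min_palindrome = 8L, min_stem = 12L, gc_target = 55,
       gc_window = 3, scan_both_strands = FALSE, seed = 1L,
       restarts = 8L, max_rounds = 10000L,
       stop_codons = c("TAA", "TGA"),
       flank5 = "GCGGCCGC", flank3 = "TTAATTAA",
       motif_file = NULL, verbosity = 1L)
}

#' Load a run configuration
#'
#' Reads a YAML key-value file, applies the documented defaults for absent
#' keys (rare-codon threshold 0.20, minimum hairpin stem 12, GC window
#' +/-3, ...), and rejects unknown keys or type mismatches.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  num_keys <- c("threshold", "min_at_run", "min_direct_repeat",
                "min_palindrome", "min_stem", "gc_target", "gc_window",
                "seed", "restarts", "max_rounds", "verbosity")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]])) {
      stop("type mismatch for config key '", k, "': expected a number",
           call. = FALSE)
    }
  }
  if (!is.logical(cfg$scan_both_strands)) {
    stop("type mismatch for config key 'scan_both_strands': ",
         "expected true/false", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Build design constraints from a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A [design_constraints()] object.
#' @export
constraints_from_config <- function(cfg) {
  motifs <- if (!is.null(cfg$motif_file)) {
    read_motif_set(cfg$motif_file)
  } else {
    default_motif_set()
  }
  design_constraints(motifs = motifs,
                     min_at_run = cfg$min_at_run,
                     min_direct_repeat = cfg$min_direct_repeat,
                     min_palindrome = cfg$min_palindrome,
                     min_stem = cfg$min_stem,
                     gc_target = cfg$gc_target,
                     gc_window = cfg$gc_window,
                     scan_both_strands = cfg$scan_both_strands)
}
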