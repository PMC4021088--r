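# Seeded synthetic-data generators: random proteins, GC-biased CDS sets,
# feature-planted sequences and Ct experiments, so every stage of the
# pipeline is testable without downloads.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Random protein sequence
#'
#' @param n_residues Length (>= 1).
#' @param seed Integer seed (optional).
#' @return Protein string, residues uniform over the 20 amino acids.
#' @export
random_protein <- function(n_residues, seed = NULL) {
  if (n_residues < 1L) stop("n_residues must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n_residues, replace = TRUE), collapse = "")
}

#' Synthetic coding-sequence set with controllable third-position GC bias
#'
#' Emulates a host training corpus (e.g. a set of GC-rich monocot coding
#' sequences) for building codon-usage tables.  Each CDS starts with ATG,
#' has a stop-free body, and at every degenerate position the codon is
#' drawn from the synonymous codons with G/C-ending codons chosen with
#' probability `gc3_bias`.
#'
#' @param n_genes Number of sequences.
#' @param mean_len_codons Mean CDS length in codons (lengths are Poisson
#'   around this mean, floored at 10).
#' @param gc3_bias Probability that a degenerate third position is G or C,
#'   in `[0, 1]`.
#' @param seed Integer seed (optional).
#' @return Character vector of CDS strings.
#' @export
synthetic_cds_set <- function(n_genes, mean_len_codons = 300L,
                              gc3_bias = 0.5, seed = NULL) {
  stopifnot(gc3_bias >= 0, gc3_bias <= 1, n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  fams <- codon_families()
  fams <- fams[names(fams) != "*"]
  third <- lapply(fams, function(f) substr(f, 3, 3) %in% c("G", "C"))
  vapply(seq_len(n_genes), function(i) {
    len <- max(10L, stats::rpois(1, mean_len_codons))
    aas <- c("M", sample(AA20, len - 1L, replace = TRUE))
    codons <- vapply(aas, function(aa) {
      f <- fams[[aa]]
      is_gc <- third[[aa]]
      if (all(is_gc) || !any(is_gc)) return(sample(f, 1))
      pool <- if (stats::runif(1) < gc3_bias) f[is_gc] else f[!is_gc]
      if (length(pool) == 1L) pool else sample(pool, 1)
    }, character(1))
    paste(codons, collapse = "")
  }, character(1))
}

#' Random DNA free of screening violations
#'
#' Rejection-samples uniform(ish) random DNA at the constraint's target GC
#' until [screen()] reports no violations; used as a clean backbone for
#' planting known features.  Errors after `max_tries` rejections.
#'
#' @param length Sequence length.
#' @param constraints A [design_constraints()] object.
#' @param seed Integer seed (optional).
#' @param max_tries Rejection cap (default 1000).
#' @return Clean DNA string of the requested length.
#' @export
random_clean_dna <- function(length, constraints = design_constraints(),
                             seed = NULL, max_tries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  p_gc <- constraints$gc_target / 100
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2,
             G = p_gc / 2, T = (1 - p_gc) / 2)
  for (i in seq_len(max_tries)) {
    s <- paste(sample(DNA_BASES, length, replace = TRUE,
                      prob = probs[DNA_BASES]), collapse = "")
    if (nrow(screen(s, constraints)$violations) == 0L) return(s)
  }
  stop("could not generate a clean backbone in ", max_tries, " tries",
       call. = FALSE)
}

#' Plant known features into a backbone sequence
#'
#' Overwrites stretches of `base_seq` with the requested features and
#' returns the modified sequence together with a ground-truth manifest of
#' the violations a screen should report.  Supported kinds:
#' `motif` (payload = motif string), `at_run` (payload = run length),
#' `hairpin` (payload = c(stem_len, loop_len); arms drawn at 75% GC so the
#' planted arms do not themselves form A/T runs), `direct_repeat`
#' (payload = c(unit_len, second_position)).
#'
#' @param base_seq Backbone DNA.
#' @param features List of lists with elements `kind`, `payload`,
#'   `position` (1-based start).
#' @param seed Integer seed for randomised payload content (optional).
#' @param min_at_run A/T-run threshold used to record the secondary
#'   `at_run` violations an all-A/T motif payload (e.g. AATAAA) genuinely
#'   introduces (default 6, matching the default constraints).
#' @return List with `sequence` and `manifest` (data frame `kind`,
#'   `start`, `end`, `payload`).
#' @export
plant_features <- function(base_seq, features, seed = NULL,
                           min_at_run = 6L) {
  s <- strsplit(check_dna(base_seq, "base_seq"), "", fixed = TRUE)[[1]]
  if (!is.null(seed)) set.seed(seed)
  n <- length(s)
  occupied <- integer(0)
  rows <- list()
  gc_letters <- function(k) sample(DNA_BASES, k, replace = TRUE,
                                   prob = c(0.125, 0.375, 0.375, 0.125))
  for (f in features) {
    pos <- as.integer(f$position)
    piece <- switch(f$kind,
      motif = strsplit(toupper(f$payload), "", fixed = TRUE)[[1]],
      at_run = sample(c("A", "T"), as.integer(f$payload), replace = TRUE),
      hairpin = {
        stem <- as.integer(f$payload[1]); loop <- as.integer(f$payload[2])
        arm <- gc_letters(stem)
        c(arm, gc_letters(loop),
          rev(unname(COMPLEMENT[arm])))
      },
      direct_repeat = {
        unit_len <- as.integer(f$payload[1])
        second <- as.integer(f$payload[2])
        unit <- gc_letters(unit_len)
        at <- c(pos:(pos + unit_len - 1L), second:(second + unit_len - 1L))
        if (max(at) > n) stop("feature exceeds sequence bounds",
                              call. = FALSE)
        if (any(at %in% occupied)) stop("features overlap", call. = FALSE)
        occupied <- c(occupied, at)
        s[pos:(pos + unit_len - 1L)] <- unit
        s[second:(second + unit_len - 1L)] <- unit
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "direct_repeat", start = pos,
          end = pos + unit_len - 1L,
          payload = paste(unit, collapse = ""),
          stringsAsFactors = FALSE)
        next
      },
      stop("unknown feature kind: ", f$kind, call. = FALSE))
    at <- pos:(pos + length(piece) - 1L)
    if (max(at) > n) stop("feature exceeds sequence bounds", call. = FALSE)
    if (any(at %in% occupied)) stop("features overlap", call. = FALSE)
    occupied <- c(occupied, at)
    s[at] <- piece
    manifest_kind <- switch(f$kind, motif = "motif", at_run = "at_run",
                            hairpin = "inverted_repeat")
    rows[[length(rows) + 1L]] <- data.frame(
      kind = manifest_kind, start = pos, end = max(at),
      payload = paste(piece, collapse = ""), stringsAsFactors = FALSE)
    if (f$kind == "motif") {
      # an all-A/T motif payload genuinely is an A/T run as well
      runs <- gregexpr(sprintf("[AT]{%d,}", min_at_run), f$payload)[[1]]
      if (runs[1] != -1L) {
        len <- attr(runs, "match.length")
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "at_run", start = pos + as.integer(runs) - 1L,
          end = pos + as.integer(runs) + len - 2L,
          payload = substring(f$payload, runs, runs + len - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               payload = character(0), stringsAsFactors = FALSE)
  list(sequence = paste(s, collapse = ""), manifest = manifest)
}

#' Planted-feature screening fixture
#'
#' Generates a clean backbone by rejection sampling against [screen()],
#' plants the requested features, and re-screens; regenerates (up to
#' `max_tries`) until the screen hits match the manifest exactly, so the
#' planted features are provably the only violations.  This is the central
#' ground-truth coupling used to test the scanners.
#'
#' @param length Backbone length.
#' @param features Feature list as for [plant_features()].
#' @param constraints A [design_constraints()] object.
#' @param seed Integer seed.
#' @param max_tries Regeneration cap (default 50).
#' @return List with `sequence`, `manifest`, and `report` (the
#'   `screen_report` of the planted sequence).
#' @export
planted_screen_fixture <- function(length, features,
                                   constraints = design_constraints(),
                                   seed = 1L, max_tries = 50L) {
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    backbone <- random_clean_dna(length, constraints)
    planted <- plant_features(backbone, features)
    rep <- screen(planted$sequence, constraints)
    v <- rep$violations[rep$violations$kind != "gc_window", , drop = FALSE]
    m <- planted$manifest
    hit_keys <- sort(paste(v$kind, v$start))
    want_keys <- sort(paste(m$kind, m$start))
    if (identical(hit_keys, want_keys)) {
      return(list(sequence = planted$sequence, manifest = m, report = rep))
    }
  }
  stop("could not build a fixture whose screen matches its manifest in ",
       max_tries, " tries", call. = FALSE)
}

#' Synthetic low-GC "native reporter" coding sequence
#'
#' A synthetic stand-in for a native low-GC reporter gene as it would
#' arrive at the design stage: a ~45% GC CDS (third-position bias 0.43)
#' carrying five planted excluded motifs — two polyadenylation signals, an
#' AU-rich instability element and both splice-site consensus motifs —
#' inserted codon-aligned so the reading frame stays stop-free.  Used to
#' re-enact the native-to-synthetic redesign at desk scale.
#'
#' @param length_codons CDS length in codons (default 400).
#' @param seed Integer seed.
#' @return DNA string starting with ATG, stop-free, length divisible by 3.
#' @export
native_like_cds <- function(length_codons = 400L, seed = 1L) {
  base <- synthetic_cds_set(1, length_codons, gc3_bias = 0.43, seed = seed)
  codons <- split_codons(base)
  n <- length(codons)
  put <- function(codons, frac, replacement) {
    at <- max(2L, min(n - length(replacement), round(frac * n)))
    codons[at:(at + length(replacement) - 1L)] <- replacement
    codons
  }
  # each replacement embeds one default excluded motif, in frame
  codons <- put(codons, 0.10, c("AAT", "AAA"))          # AATAAA polyA
  codons <- put(codons, 0.28, c("AAT", "AAT"))          # AATAAT polyA
  codons <- put(codons, 0.45, c("ATT", "TAC"))          # ATTTA instability
  codons <- put(codons, 0.63, c("GGT", "AAG", "TCC"))   # GGTAAGT donor
  codons <- put(codons, 0.80, c("TTT", "TCA", "GCA"))   # TTTTCAG acceptor
  paste(codons, collapse = "")
}

#' Simulate a comparative-CT experiment with known ground truth
#'
#' Generates replicate Ct pairs for two co-delivered transcripts whose
#' true abundance ratio is `true_fold` under amplification efficiency
#' `efficiency`, plus Gaussian measurement noise, and an ideal dilution
#' series with slope `-1/log10(1 + E)`.
#'
#' @param true_fold True abundance of condition "a" relative to "b" (> 0).
#' @param efficiency Amplification efficiency as a fraction in (0, 1.2].
#' @param sigma Ct measurement noise standard deviation (>= 0).
#' @param n_replicates Replicate pairs to simulate.
#' @param seed Integer seed (optional).
#' @param base_ct Mean Ct of condition "b" (default 20).
#' @param dilution_points Number of 10-fold dilution points (default 4).
#' @return A `ct_experiment`: list with `replicates` (data frame
#'   `condition`, `ct`), `dilution_series` (data frame `log10_input`,
#'   `ct`), and the true parameters.
#' @export
simulate_ct_data <- function(true_fold, efficiency = 1, sigma = 0,
                             n_replicates = 3L, seed = NULL,
                             base_ct = 20, dilution_points = 4L) {
  stopifnot(true_fold > 0, efficiency > 0, efficiency <= 1.2, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  dct <- log(true_fold) / log(1 + efficiency)
  ct_b <- base_ct + stats::rnorm(n_replicates, 0, sigma)
  ct_a <- base_ct - dct + stats::rnorm(n_replicates, 0, sigma)
  reps <- data.frame(
    condition = rep(c("a", "b"), each = n_replicates),
    ct = c(ct_a, ct_b), stringsAsFactors = FALSE)
  x <- -(seq_len(dilution_points) - 1L)
  dil <- data.frame(log10_input = x,
                    ct = base_ct - x / log10(1 + efficiency) +
                      stats::rnorm(dilution_points, 0, sigma))
  structure(list(replicates = reps, dilution_series = dil,
                 true_fold = true_fold, efficiency = efficiency,
                 sigma = sigma),
            class = "ct_experiment")
}

#' Estimate fold change from a simulated or measured Ct experiment
#'
#' @param experiment A `ct_experiment` (or any list with a `replicates`
#'   data frame holding `condition` and `ct`).
#' @param efficiency Efficiency fraction used in the fold computation.
#' @return Fold change of condition "a" relative to condition "b".
#' @export
estimate_fold <- function(experiment, efficiency = 1) {
  r <- experiment$replicates
  comparative_ct_fold(r$ct[r$condition == "a"],
                      r$ct[r$condition == "b"],
                      efficiency = efficiency)
}
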