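# Constrained Monte Carlo reverse translation with iterative repair.

#' Monte Carlo reverse translation
#'
#' Draws a codon for each residue independently from the allowed sampling
#' distribution for that amino acid (host codon-usage frequencies after
#' rare-codon filtering).  The same seed always yields the same sequence.
#'
#' @param protein Protein string over the 20 amino acids.
#' @param allowed An [filter_rare_codons()] `allowed_codon_set`.
#' @param seed Integer seed for the draw (optional; `NULL` uses the current
#'   RNG state).
#' @return DNA string, `3 * nchar(protein)` long, translating back to
#'   `protein`.
#' @export
reverse_translate <- function(protein, allowed, seed = NULL) {
  stopifnot(inherits(allowed, "allowed_codon_set"))
  aas <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  if (length(aas) == 0L) stop("empty protein", call. = FALSE)
  miss <- !(aas %in% names(allowed$allowed))
  if (any(miss)) {
    i <- which(miss)[1]
    stop(sprintf("unencodable residue '%s' at position %d", aas[i], i),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  codons <- character(length(aas))
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    p <- allowed$allowed[[aa]]
    codons[idx] <- if (length(p) == 1L) {
      names(p)
    } else {
      sample(names(p), length(idx), replace = TRUE, prob = p)
    }
  }
  paste(codons, collapse = "")
}

# Exponentially tilt each family's sampling distribution toward (beta > 0)
# or away from (beta < 0) G+C-rich codons: p'(c) ~ p(c) * exp(beta * gc(c)).
# `probs` is a named list: amino acid -> named probability vector.
tilt_probs <- function(probs, beta) {
  lapply(probs, function(p) {
    q <- p * exp(beta * codon_gc(names(p)))
    q / sum(q)
  })
}

# Uniform sampling distributions over the full synonymous families (rare
# codons admitted); the escalation pool for stubborn violations.
full_family_probs <- function() {
  fams <- codon_families()
  fams <- fams[names(fams) != "*"]
  lapply(fams, function(f) stats::setNames(rep(1 / length(f), length(f)), f))
}

# Mix the allowed distributions with weight w of the uniform full-family
# distribution (support widens to every synonymous codon).
blend_with_full <- function(probs, w = 0.5) {
  full <- full_family_probs()
  lapply(stats::setNames(nm = names(full)), function(aa) {
    u <- full[[aa]]
    p <- u * 0
    got <- probs[[aa]]
    p[names(got)] <- got
    (1 - w) * p + w * u
  })
}

# Expected number of G+C bases contributed by one codon of each amino acid
# under a tilted distribution.
expected_gc_per_aa <- function(probs, beta) {
  vapply(probs, function(p) {
    g <- codon_gc(names(p))
    q <- p * exp(beta * g)
    sum(q * g) / sum(q)
  }, numeric(1))
}

# Solve for the tilt beta that makes the expected G+C base count of the
# residues in `aa_counts` equal `target_bases`; clamped to [-30, 30] when
# the target is unattainable.
solve_gc_tilt <- function(probs, aa_counts, target_bases) {
  f <- function(beta) {
    sum(aa_counts * expected_gc_per_aa(probs, beta)[names(aa_counts)]) -
      target_bases
  }
  lo <- -30; hi <- 30
  if (f(lo) >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
}

# Lexicographic (violation count, GC distance beyond window) score;
# smaller is better.
repair_score <- function(report, constraints) {
  c(nrow(report$violations[report$violations$kind != "gc_window", ,
                           drop = FALSE]),
    max(0, abs(report$gc_percent - constraints$gc_target) -
          constraints$gc_window))
}

score_less <- function(a, b) {
  a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
}

#' Iterative violation repair with GC steering
#'
#' Automates the candidate-filtering and refinement step of
#' silencing-resistant transgene design: screen the candidate, and while
#' violations remain (or GC is outside the target window), resample every
#' codon overlapping a violation — expanded by one codon on each side —
#' from the allowed distributions, exponentially tilted so the expected GC
#' of the resampled sequence lands on the target.  The encoded protein is
#' preserved at every step.  After `max_rounds` the best candidate seen is
#' returned, scored lexicographically by (violation count, GC distance
#' beyond the window).
#'
#' @param dna Candidate CDS (must translate to `protein`).
#' @param protein The target protein.
#' @param constraints A [design_constraints()] object.
#' @param allowed An `allowed_codon_set`.
#' @param seed Integer seed (optional).
#' @param max_rounds Maximum resampling rounds (>= 1; default 10000).
#' @param escalate_after After this many rounds without improvement,
#'   violating codons are resampled from the full synonymous family (rare
#'   codons admitted) instead of only the allowed set — the automated
#'   analogue of manually editing a stubborn feature that the common-codon
#'   pool cannot break (default 10).
#' @return A `design_result`: list with `sequence`, `protein`,
#'   `violations_remaining`, `converged`, `rounds_used`, `seed`, `metrics`
#'   and `score_history` (per-round best-so-far scores).
#' @export
repair <- function(dna, protein, constraints = design_constraints(),
                   allowed, seed = NULL, max_rounds = 10000L,
                   escalate_after = 10L) {
  if (max_rounds < 1L) {
    stop("invalid parameter: max_rounds must be >= 1", call. = FALSE)
  }
  dna <- check_dna(dna, "dna")
  protein <- toupper(protein)
  if (as.character(translate_cds(dna)) != protein) {
    stop("dna does not translate to the supplied protein", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  n_codons <- length(aas)
  codons <- split_codons(dna)
  target_bases_total <- constraints$gc_target / 100 * 3 * n_codons
  # mild global tilt: expected GC of a full redraw equals the target;
  # used for local repairs so they do not drift the sequence composition.
  # If the filtered pool cannot reach the target for this amino-acid
  # composition (tilt clamps), rare codons are admitted via a blended
  # pool so the window becomes attainable.
  # 10% full-family admixture keeps resampling ergodic: regions where the
  # filtered pool is single-codon (and its preferred fill itself violates
  # a rule) would otherwise be resampled to the same bases every round.
  # Should even that pool be unable to reach the target GC for this
  # composition (the tilt clamps), the admixture is widened.
  aa_tab <- table(aas)
  steer <- blend_with_full(allowed$allowed, 0.1)
  beta_global <- solve_gc_tilt(steer, aa_tab, target_bases_total)
  if (abs(beta_global) >= 30) {
    steer <- blend_with_full(allowed$allowed, 0.5)
    beta_global <- solve_gc_tilt(steer, aa_tab, target_bases_total)
  }
  sampler <- tilt_probs(steer, beta_global)

  best <- NULL
  best_score <- c(Inf, Inf)
  history <- list()
  rounds <- 0L
  stale <- 0L
  # exploratory pool for stubborn violations: uniform over the full
  # synonymous families, deliberately untilted so it cannot lock onto a
  # single extreme-composition choice
  escalated <- full_family_probs()
  repeat {
    seq_now <- paste(codons, collapse = "")
    rep_now <- screen(seq_now, constraints)
    sc <- repair_score(rep_now, constraints)
    if (score_less(sc, best_score)) {
      best_score <- sc
      best <- list(seq = seq_now, report = rep_now, rounds = rounds)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    history[[length(history) + 1L]] <- best_score
    if (nrow(rep_now$violations) == 0L || rounds >= max_rounds) break

    # codons overlapping any violation, +/- 1 codon on each side;
    # structural violations are repaired locally (the global tilt keeps
    # composition on target), and only a pure GC breach triggers a full
    # redraw
    v <- rep_now$violations
    sv <- v[v$kind != "gc_window", , drop = FALSE]
    if (nrow(sv) > 0L) v <- sv
    arm <- rbind(cbind(v$start, v$end),
                 cbind(v$partner_start, v$partner_end))
    arm <- arm[!is.na(arm[, 1]), , drop = FALSE]
    idx <- unique(unlist(apply(arm, 1, function(iv) {
      lo <- max(1L, ceiling(iv[1] / 3) - 1L)
      hi <- min(n_codons, ceiling(iv[2] / 3) + 1L)
      lo:hi
    }, simplify = FALSE)))

    # GC steering: resample under the global tilt, whose expectation for a
    # full redraw is the target GC; an out-of-window sequence is fully
    # redrawn (the gc_window violation spans it), pulling GC onto target,
    # while local repairs stay stochastic and composition-neutral
    cnt <- table(aas[idx])
    tilted <- if (stale >= escalate_after) escalated else sampler
    for (aa in names(cnt)) {
      at <- idx[aas[idx] == aa]
      p <- tilted[[aa]]
      codons[at] <- if (length(p) == 1L) {
        names(p)
      } else {
        sample(names(p), length(at), replace = TRUE, prob = p)
      }
    }
    rounds <- rounds + 1L
  }

  converged <- nrow(best$report$violations) == 0L
  structure(list(
    sequence = best$seq,
    protein = protein,
    violations_remaining = best$report$violations,
    converged = converged,
    rounds_used = best$rounds,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    metrics = list(gc_percent = best$report$gc_percent,
                   identity_to_reference = NA_real_,
                   codon_changes = NA_integer_),
    score_history = do.call(rbind, history)),
    class = "design_result")
}

#' Design a host-optimised synonymous coding sequence
#'
#' The full design procedure: filter rare codons from the host usage table,
#' reverse translate the protein by Monte Carlo sampling, then iteratively
#' repair motif/repeat/hairpin/GC violations — with several independent
#' seeded restarts, returning the best result.  When a native CDS is given
#' as input, its protein is designed and positional identity to the native
#' sequence is reported, mirroring the published workflow that recoded the
#' low-GC firefly and Renilla luciferase genes to a GC-rich host bias while
#' retaining 100% protein identity.
#'
#' @param input Protein string, or a native CDS (auto-detected; force with
#'   `input_type`).
#' @param table A `codon_usage_table` for the host.
#' @param constraints A [design_constraints()] object.
#' @param threshold Rare-codon cutoff passed to [filter_rare_codons()].
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param max_rounds Repair rounds per restart.
#' @param restarts Number of independent attempts (default 8); stops early
#'   at the first converged result.
#' @param input_type `"auto"`, `"protein"`, or `"cds"`.
#' @return A `design_result` (see [repair()]) with populated `metrics`
#'   (`gc_percent`, `identity_to_reference`, `codon_changes`) and
#'   `restarts_used`.
#' @export
design <- function(input, table, constraints = design_constraints(),
                   threshold = 0.20, seed = 1L, max_rounds = 10000L,
                   restarts = 8L,
                   input_type = c("auto", "protein", "cds")) {
  input_type <- match.arg(input_type)
  input <- toupper(input)
  if (input_type == "auto") {
    looks_dna <- !nzchar(gsub("[ACGT]", "", input)) &&
      nchar(input) %% 3L == 0L &&
      !inherits(tryCatch(translate_cds(input), error = function(e) e),
                "error")
    input_type <- if (looks_dna) "cds" else "protein"
  }
  if (input_type == "cds") {
    reference <- input
    prot <- translate_cds(input)
    n_stops <- attr(prot, "n_stops")
    protein <- as.character(prot)
    # keep the comparable (stop-free) portion of the native CDS
    if (n_stops > 0L) {
      reference <- substr(reference, 1L, 3L * nchar(protein))
    }
  } else {
    reference <- NULL
    protein <- input
  }
  allowed <- filter_rare_codons(table, threshold)
  best <- NULL
  restarts_used <- 0L
  for (r in seq_len(restarts)) {
    seed_r <- seed + r - 1L
    dna0 <- reverse_translate(protein, allowed, seed = seed_r)
    res <- repair(dna0, protein, constraints, allowed,
                  seed = seed_r, max_rounds = max_rounds)
    restarts_used <- r
    sc <- c(nrow(res$violations_remaining[
      res$violations_remaining$kind != "gc_window", , drop = FALSE]),
      max(0, abs(res$metrics$gc_percent - constraints$gc_target) -
            constraints$gc_window))
    if (is.null(best) || score_less(sc, best$sc)) {
      best <- list(res = res, sc = sc)
    }
    if (res$converged) break
  }
  out <- best$res
  out$seed <- as.integer(seed)
  out$restarts_used <- restarts_used
  out$metrics$gc_percent <- gc_content(out$sequence)
  if (!is.null(reference)) {
    out$metrics$identity_to_reference <-
      positional_identity(reference, out$sequence)$percent_identity
    out$metrics$codon_changes <-
      codon_change_summary(reference, out$sequence)$codons_changed
  }
  out
}

#' @export
print.design_result <- function(x, ...) {
  cat("Design result: ", nchar(x$sequence), " nt, GC ",
      x$metrics$gc_percent, "%, ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$rounds_used, " repair round(s)\n", sep = "")
  if (!is.na(x$metrics$identity_to_reference)) {
    cat("  identity to native CDS: ", x$metrics$identity_to_reference,
        "% (", x$metrics$codon_changes, " codons changed)\n", sep = "")
  }
  if (nrow(x$violations_remaining) > 0L) {
    cat("  violations remaining:", nrow(x$violations_remaining), "\n")
  }
  invisible(x)
}

#' Finalise a designed ORF into a cloning-ready insert
#'
#' Appends tandem stop codons and wraps the ORF in 5' and 3' restriction
#' sites (defaults: two stops TAA+TGA, NotI upstream, PacI downstream).
#' The finalised insert is re-screened to confirm each flanking site occurs
#' exactly once.
#'
#' @param dna Stop-free ORF body.
#' @param stop_codons Character vector of stop codons to append in order
#'   (>= 1 required).
#' @param flank5,flank3 Flanking restriction sites.
#' @return The finalised insert string.
#' @examples
#' finalize_construct("ATGGCC")
#' @export
finalize_construct <- function(dna, stop_codons = c("TAA", "TGA"),
                               flank5 = "GCGGCCGC",
                               flank3 = "TTAATTAA") {
  dna <- check_dna(dna, "dna")
  if (length(stop_codons) < 1L) {
    stop("at least one stop codon is required", call. = FALSE)
  }
  if (!all(toupper(stop_codons) %in% c("TAA", "TAG", "TGA"))) {
    stop("stop_codons must be TAA, TAG or TGA", call. = FALSE)
  }
  prot <- translate_cds(dna)
  if (attr(prot, "n_stops") > 0L) {
    stop("dna must be a stop-free ORF body", call. = FALSE)
  }
  out <- paste0(toupper(flank5), dna,
                paste(toupper(stop_codons), collapse = ""),
                toupper(flank3))
  sites <- rbind(motif_pattern(flank5, "flank5", "restriction_site"),
                 motif_pattern(flank3, "flank3", "restriction_site"))
  hits <- scan_motifs(out, unique(sites))
  for (lab in unique(hits$label)) {
    h <- hits[hits$label == lab, , drop = FALSE]
    want <- if (toupper(flank5) == toupper(flank3)) 2L else 1L
    if (nrow(h) > want) {
      stop("finalize error: site ", lab, " occurs ", nrow(h),
           " times (positions ", paste(h$start, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  out
}
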