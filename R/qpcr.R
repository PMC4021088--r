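# Transgene-discriminating qPCR: primer design on sequence polymorphisms,
# dilution-series efficiency, and comparative-CT quantification.

#' Primer melting temperature (nearest-neighbor-free rule)
#'
#' Wallace rule `2(A+T) + 4(G+C)` for primers shorter than 14 nt, and the
#' standard GC formula `64.9 + 41 * (GC - 16.4) / length` otherwise.
#' Deliberately simple and dependency-free; documented so it can be
#' swapped.
#'
#' @param primer DNA string.
#' @return Tm in degrees Celsius, one decimal.
#' @export
primer_tm <- function(primer) {
  primer <- check_dna(primer, "primer")
  n <- nchar(primer)
  gc <- n - nchar(gsub("[GC]", "", primer))
  tm <- if (n < 14L) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  round(tm, 1)
}

#' Design transgene-discriminating qPCR primer pairs
#'
#' For a native/synthetic synonymous pair (equal length, scattered
#' engineered polymorphisms) designs one primer pair per template such
#' that: both pairs amplify identical amplicon lengths from the 3' region
#' of each template; every primer carries at least one transgene-specific
#' base among its three 3'-terminal positions (so it mismatches the other
#' template exactly where extension starts); and the melting temperatures
#' of all primers are within `tm_window` of each other.  This is the assay
#' geometry that lets quantitative PCR distinguish co-delivered native and
#' recoded transgenes with equal efficiency.
#'
#' @param native,synthetic Equal-length DNA strings.
#' @param primer_len Candidate primer lengths (default 18:25).
#' @param amplicon_len Allowed amplicon length range (default c(80, 250)).
#' @param tm_window Maximum Tm spread across the four primers (default 4).
#' @param three_prime_region_fraction Fraction of the template (from the 3'
#'   end) searched for primer sites (default 0.33).
#' @return List with elements `native` and `synthetic`, each a
#'   `primer_pair`: list with `forward`, `reverse`, `amplicon_start`,
#'   `amplicon_end`, `amplicon_length`, `discriminating_positions`
#'   (distance from each primer's 3' end, 0 = terminal base),
#'   `tm_forward`, `tm_reverse`.
#' @export
design_discriminating_primers <- function(native, synthetic,
                                          primer_len = 18:25,
                                          amplicon_len = c(80L, 250L),
                                          tm_window = 4,
                                          three_prime_region_fraction = 0.33) {
  a <- check_dna(native, "native")
  b <- check_dna(synthetic, "synthetic")
  if (nchar(a) != nchar(b)) {
    stop("templates must be equal length (synonymous pair)", call. = FALSE)
  }
  n <- nchar(a)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  poly <- which(ca != cb)
  region_start <- max(1L, n - as.integer(ceiling(
    three_prime_region_fraction * n)) + 1L)
  poly <- poly[poly >= region_start]
  if (length(poly) == 0L) {
    stop("no discriminating site: templates are identical in the 3' region",
         call. = FALSE)
  }
  # forward primer 3'-anchored on polymorphism p, reverse primer (on the
  # reverse strand) 3'-anchored on polymorphism q; same coordinates on both
  # templates => equal amplicon lengths by construction
  for (p in poly) {
    for (q in rev(poly[poly > p])) {
      for (lf in primer_len) {
        if (p - lf + 1L < 1L) next
        for (lr in primer_len) {
          if (q + lr - 1L > n) next
          amp_len <- (q + lr - 1L) - (p - lf + 1L) + 1L
          if (amp_len < amplicon_len[1] || amp_len > amplicon_len[2]) next
          fwd_a <- substring(a, p - lf + 1L, p)
          fwd_b <- substring(b, p - lf + 1L, p)
          rev_a <- reverse_complement(substring(a, q, q + lr - 1L))
          rev_b <- reverse_complement(substring(b, q, q + lr - 1L))
          tms <- c(primer_tm(fwd_a), primer_tm(rev_a),
                   primer_tm(fwd_b), primer_tm(rev_b))
          if (diff(range(tms)) > tm_window) next
          mk <- function(fwd, rv, tmf, tmr) {
            structure(list(
              forward = fwd, reverse = rv,
              amplicon_start = p - lf + 1L, amplicon_end = q + lr - 1L,
              amplicon_length = amp_len,
              discriminating_positions = list(
                forward = (p - (p - lf + 1L):p)[ca[(p - lf + 1L):p] !=
                                                  cb[(p - lf + 1L):p]],
                reverse = (((q:(q + lr - 1L)) - q)[ca[q:(q + lr - 1L)] !=
                                                     cb[q:(q + lr - 1L)]])),
              tm_forward = tmf, tm_reverse = tmr), class = "primer_pair")
          }
          return(list(native = mk(fwd_a, rev_a, tms[1], tms[2]),
                      synthetic = mk(fwd_b, rev_b, tms[3], tms[4])))
        }
      }
    }
  }
  stop("no discriminating site: no primer geometry satisfies the ",
       "amplicon/Tm constraints in the 3' region", call. = FALSE)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair: amplicon [", x$amplicon_start, ", ", x$amplicon_end,
      "] (", x$amplicon_length, " bp)\n",
      "  F 5'-", x$forward, "-3'  Tm ", x$tm_forward, "\n",
      "  R 5'-", x$reverse, "-3'  Tm ", x$tm_reverse, "\n", sep = "")
  invisible(x)
}

#' Amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10 relative input; efficiency is
#' `(10^(-1/slope) - 1) * 100`, so the ideal slope of -3.3219 cycles per
#' decade gives 100%.
#'
#' @param dilution_series Data frame or list with components/columns
#'   `log10_input` and `ct`, at least 3 points spanning >= 2 log10 units.
#' @return List with `slope`, `efficiency_percent`, `r_squared`.
#' @examples
#' s <- data.frame(log10_input = 0:-3, ct = 18 + 3.3219 * (0:3))
#' amplification_efficiency(s)$efficiency_percent
#' @export
amplification_efficiency <- function(dilution_series) {
  x <- dilution_series$log10_input
  y <- dilution_series$ct
  if (length(x) < 3L) {
    stop("insufficient points: a dilution series needs >= 3 points",
         call. = FALSE)
  }
  if (diff(range(x)) < 2) {
    stop("dilution series must span at least 2 log10 units", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate series: zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope,
       efficiency_percent = (10^(-1 / slope) - 1) * 100,
       r_squared = stats::cor(x, y)^2)
}

#' Comparative-CT fold change
#'
#' The comparative cycle-threshold method: for two transcripts amplified
#' with equal efficiency from the same sample (e.g. co-delivered native and
#' recoded transgenes), fold = `(1 + E)^(Ct_b - Ct_a)` — transcript `a`
#' relative to transcript `b`.  When reference-normalised ΔΔCt values are
#' in hand use [relative_copy_number()].
#'
#' @param ct_a,ct_b Ct values (cycles, > 0); scalars or equal-length
#'   replicate vectors (replicates are averaged).
#' @param efficiency Amplification efficiency as a fraction (default 1 =
#'   100%).
#' @return Fold change of `a` relative to `b` (numeric scalar).
#' @examples
#' comparative_ct_fold(20, 21)        # 2-fold
#' @export
comparative_ct_fold <- function(ct_a, ct_b, efficiency = 1) {
  stopifnot(all(ct_a > 0), all(ct_b > 0),
            efficiency > 0, efficiency <= 1.2)
  (1 + efficiency)^(mean(ct_b) - mean(ct_a))
}

#' Relative copy number by the 2^-ΔΔCt method
#'
#' `2^-ΔΔCt` with
#' `ΔΔCt = (ct_target - ct_reference) - (ct_target_calibrator -
#' ct_reference_calibrator)`: target abundance in a sample relative to a
#' calibrator sample, each normalised to a reference gene, as used for
#' transgene copy-number estimation against a single-copy host reference.
#'
#' @param ct_target,ct_reference Sample Ct values (target and reference
#'   gene).
#' @param ct_target_calibrator,ct_reference_calibrator Calibrator Ct
#'   values.
#' @return Relative copy-number ratio.
#' @export
relative_copy_number <- function(ct_target, ct_reference,
                                 ct_target_calibrator,
                                 ct_reference_calibrator) {
  stopifnot(all(c(ct_target, ct_reference, ct_target_calibrator,
                  ct_reference_calibrator) > 0))
  ddct <- (mean(ct_target) - mean(ct_reference)) -
    (mean(ct_target_calibrator) - mean(ct_reference_calibrator))
  2^(-ddct)
}

#' Read / write Ct data as tab-delimited text
#'
#' Columns: `sample`, `condition`, `ct`, optional `log10_input`.
#'
#' @param path File path.
#' @param ct_data Data frame of Ct measurements.
#' @return `read_ct_data()` returns the data frame; `write_ct_data()`
#'   returns `path` invisibly.
#' @export
read_ct_data <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_ct_data
#' @export
write_ct_data <- function(ct_data, path) {
  utils::write.table(ct_data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
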