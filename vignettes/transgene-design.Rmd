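---
title: "Designing silencing-resistant transgenes with recodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing silencing-resistant transgenes with recodon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recodon)
```

## The problem

Transgenes sourced from distant organisms are often expressed poorly in
plant hosts, and a recurring cause is the sequence itself rather than the
protein it encodes.  A coding sequence whose composition is far from the
host's — low GC in a GC-rich monocot such as sugarcane, rare codons,
AT-rich stretches — can carry cryptic polyadenylation signals that
truncate the transcript, AU-rich elements that destabilise the mRNA,
splice-site consensus motifs that trigger unintended intron recognition,
and repeats or hairpin-forming inverted repeats that can seed
post-transcriptional gene silencing.  The classic remedy is to resynthesise
the gene: keep the protein, exploit the degeneracy of the genetic code, and
choose among synonymous codons so that the DNA looks like a well-behaved
host gene.  The firefly and *Renilla* luciferase reporters recoded this way
for sugarcane (from 45% and 36.5% GC up to 55% and 52%, at 75% nucleotide
identity to the native genes and 100% protein identity) are the motivating
example for this package.

`recodon` implements that design procedure as a reusable, fully seeded
toolkit: build a host codon-usage table, drop rare codons, reverse
translate by Monte Carlo sampling, screen for every excluded feature, and
repair violations iteratively — plus the verification metrics and the
qPCR quantification math used to show that the redesigned gene behaves as
intended.

## The design procedure

### Codon usage and rare-codon filtering

A `codon_usage_table` tallies the codons of a training set of host coding
sequences (`build_usage_table()`) or is parsed from a Kazusa-style export
(`parse_kazusa_table()`; counts are trusted, printed frequencies are
recomputed).  The quantity that matters downstream is the *relative
synonymous frequency*: each codon's share within its amino-acid family.

`filter_rare_codons()` removes codons whose family share falls below a
threshold (default 0.20) and renormalises the survivors.  Two choices here
are ours rather than inherited facts.  First, the threshold is interpreted
on the per-family share, because only that makes a single cutoff
meaningful across 2-codon and 6-codon families; an absolute
per-thousand-codon interpretation would silently exempt large families.
Second, if an entire family falls below the threshold, the
highest-frequency codon is retained (ties broken alphabetically) so every
protein remains encodable; zero-count families fall back to uniform
frequencies so sparse training sets cannot divide by zero.

### Reverse translation

`reverse_translate()` draws a codon for each residue independently from
the filtered, renormalised distribution.  The draw is seeded and
reproducible: the same seed, protein and allowed set give the identical
sequence.

### Screening

`screen()` unions six finders, each reporting 1-based closed intervals
with the offending subsequence attached (`substr(seq, start, end)` always
equals the `matched` column):

* **Degenerate motifs** (`scan_motifs()`): IUPAC patterns matched with
  full degeneracy, all overlapping occurrences, forward strand by default.
  The shipped default set covers canonical plant polyadenylation signals
  (AATAAA and variants), the AU-rich instability element (ATTTA), and
  splice donor/acceptor consensus motifs; it is a starting point and is
  fully replaceable from a tab-delimited file, since any real project will
  curate its own exclusion list.
* **A/T runs** (`find_at_runs()`): maximal stretches of A and/or T of at
  least `min_at_run` (default 6).
* **Direct repeats** (`find_direct_repeats()`): pairs of identical
  non-overlapping substrings of at least `min_direct_repeat` (default 10),
  reported as maximal matches.
* **Inverted repeats** (`find_inverted_repeats()`): arm + arbitrary loop +
  reverse-complement arm, arms at least `min_stem` (default 12) — the DNA
  signature of a transcript that can fold into a double-stranded stem of
  12 bp or more.  Matching is exact reverse complement: no G·U wobble and
  no mismatches, which keeps the rule unambiguous and lets an exhaustive
  oracle verify the scanner exactly.  Thermodynamic folding is out of
  scope.
* **Palindromes** (`find_palindromes()`): even-length substrings equal to
  their own reverse complement, at least `min_palindrome` (default 8).
  These are the zero-loop special case of inverted repeats; both finders
  are exposed because the screening tradition treats them as separate
  rules with separate length thresholds.
* **Restriction sites**: NotI (GCGGCCGC) and PacI (TTAATTAA) by default —
  the cloning flanks must remain unique in the final construct.  Both
  defaults are their own reverse complements, so strandedness is moot.

GC content outside `gc_target ± gc_window` (default 55 ± 3, the window
around the host's coding average) is reported as a `gc_window` violation
spanning the whole sequence.

Of these thresholds only the 12 bp stem and the 20% codon cutoff are
inherited from the motivating design; `min_at_run = 6`,
`min_direct_repeat = 10` and `min_palindrome = 8` are conventional
gene-synthesis screening values, and all are plain arguments.

### Iterative repair

`repair()` automates what was historically a candidate-filtering step
followed by manual refinement:

1. Screen the candidate.  If it is clean and GC is in the window, stop.
2. Otherwise resample every codon overlapping a violation, expanded by one
   codon on each side.  A pure GC breach spans the whole sequence, so that
   case is a full redraw; structural violations are repaired locally.
3. Track the best candidate seen, scored lexicographically by
   (violation count, GC distance beyond the window); after `max_rounds`
   return it with `converged = FALSE`.

The encoded protein is invariant at every step, so converged or not, the
output is always a synonymous recoding.

**GC steering.**  Resampling uses an exponentially tilted version of the
allowed distributions, \(p'(c) \propto p(c)\,e^{\beta\,\mathrm{gc}(c)}\),
with \(\beta\) solved (by `uniroot`) so that the expected GC of a full
redraw equals the target.  This subsumes "bias toward the highest-GC
codon" as \(\beta \to \infty\), converges in a handful of rounds, and —
because local repairs use the same mild global tilt — keeps targeted fixes
composition-neutral instead of dragging the sequence off target.

**Escalation.**  Two failure modes cannot be fixed under the filtered pool
at all: a violation whose codons all belong to single-allowed-codon amino
acids (no resampling can change the bases), and an amino-acid composition
whose attainable GC range under the filtered pool misses the target window
entirely (the tilt clamps).  These are exactly the situations that
historically required manual editing.  `repair()` automates the manual
step: after `escalate_after` (default 10) rounds without improvement,
violating codons are resampled from the *full* synonymous family — uniform
and deliberately untilted, so the escape draw cannot lock onto a single
extreme-composition choice — and when the target GC is unattainable under
the filtered pool, the steering distribution is blended half-and-half with
the full families so the window becomes reachable.  A few rare codons may
therefore appear in the output, precisely where the constraint set forced
them.

`design()` wires the stages together — filter, reverse translate, repair —
with `restarts` independently seeded attempts (restart *r* uses
`seed + r − 1`), stopping at the first converged result and otherwise
returning the best scored.  With a native CDS as input it also reports
positional identity to the native gene and a codon-change summary.
`finalize_construct()` then appends tandem stop codons (default TAA+TGA, a
configurable guess — the deposited constructs' exact pair is not stated in
the running text we reimplement from) and wraps the ORF in NotI/PacI
flanks, re-screening to confirm each site occurs exactly once.

## Verification metrics

`gc_content()`, `positional_identity()` (the natural metric for a
synonymous recoding, which preserves length — gaps cannot occur),
`global_identity()` (Needleman–Wunsch fallback for unequal lengths, via
`Biostrings::pairwiseAlignment`), and `codon_change_summary()` (codons
changed and base changes by codon position; synonymous recoding
concentrates changes at third positions).  Identity and GC are reported to
one decimal; comparisons against published integers should use
nearest-integer tolerance.  Whether a published identity figure counts
flanks and stops or the bare ORF is ambiguous; these metrics compare bare
ORFs.

## qPCR quantification math

The co-delivery assay that demonstrates a redesign's effect on transcript
abundance needs primers that distinguish two synonymous transgenes in the
same sample.  `design_discriminating_primers()` searches the 3' region
(default the last third) for polymorphic positions and anchors each
primer's 3' terminus on one, with both pairs placed at identical template
coordinates, so amplicon lengths are equal by construction and every
primer mismatches the other template at the extension-critical end.
Melting temperature uses the nearest-neighbor-free Wallace/GC rule
(documented in `primer_tm()`, deliberately simple and swappable).

`amplification_efficiency()` fits Ct against log10 input:
\(E = (10^{-1/\text{slope}} - 1) \times 100\), so the ideal slope of
−3.3219 cycles per decade gives 100%.  `comparative_ct_fold()` implements
the comparative-CT method, fold \(= (1+E)^{\Delta C_T}\): the direct
two-transcript form is the default because in a co-delivery with equimolar
input the delivered DNA is its own normaliser.  The reference-normalised
form is `relative_copy_number()`, \(2^{-\Delta\Delta C_T}\), as used for
transgene copy-number estimation against a single-copy host gene.

## Synthetic data and what passing tests mean

Every stage is testable offline through seeded generators:
`random_protein()`, `synthetic_cds_set()` (third-position GC bias
`gc3_bias` controls corpus composition), `random_clean_dna()` (rejection
sampling against `screen()`, capped at 1000 tries),
`plant_features()`/`planted_screen_fixture()` (features planted on a clean
backbone, regenerated until the screen hits equal the manifest — the
ground-truth coupling the scanner tests rest on), `native_like_cds()` (a
~45% GC CDS with five planted excluded motifs, the desk-scale stand-in for
a native low-GC reporter), and `simulate_ct_data()` (replicate Ct pairs
with known true fold and noise, plus a dilution series with the matching
slope).

The generator settings are fixed study conditions, not tuning knobs: the
host corpus uses `gc3_bias = 0.8` because that reproduces a coding-average
GC of ~55.7% (the documented host average), 71 training sequences of ~300
codons; the native-like fixture uses `gc3_bias = 0.43`, which lands its GC
near the 45% of the native firefly reporter.

Synthetic corpora emulate composition, not biology: they have no real
promoter context, no codon-pair effects, no expression data.  A passing
suite shows the algorithms do what they claim on sequences with the stated
statistical properties — it does not show that a particular redesigned
gene will express well in a particular host.

## Numerical choices and problem sizes

* Coordinates are 1-based closed intervals throughout, the R/Bioconductor
  convention (`substr`-compatible).
* Repair scoring is lexicographic (violations, then GC distance beyond the
  window); ties keep the earlier candidate.  `max_rounds` defaults to
  10000; the test suite and acceptance script use 200–300, which the
  convergence statistics (typically < 30 rounds) make ample.
* The tilt solver runs on `[-30, 30]` with clamping; a clamped solve is
  the signal that triggers pool blending.
* Scanner correctness is asserted against exhaustive brute-force oracles
  on hundreds of random 500-nt sequences; the design round-trip suite runs
  500 random proteins of 50–300 residues (protein identity, zero
  violations, GC in window).  The palindrome oracle enumerates lengths up
  to 30 nt, far beyond anything random sequence produces.
* Degenerate inputs error early and descriptively: frames not divisible by
  three, non-ACGT characters, internal stops, empty FASTA files, duplicate
  ids, unknown configuration keys, thresholds outside their domains.

## Known limitations

* Some residue contexts are provably undesignable under the default
  thresholds, and `design()` then reports `converged = FALSE` with the
  best candidate rather than pretending otherwise.  The sharpest example
  is a Met/Ile-dense stretch such as Met-Ile-Ile-Met-Ile: every Met and
  Ile codon begins with AT, so with `a`,`b` the free third bases of the
  two inner Ile codons, `b = C` creates the palindrome ATCATGAT
  (Ile·Met·Ile), `b ∈ {A,T}` forces `a = C` to break the 8-base A/T run
  ATaATbAT, and `a = C` creates the palindrome ATGATCAT (Met·Ile·Ile).
  Every synonymous choice violates the 8 bp palindrome rule or the 6 bp
  A/T-run rule.  Demanding exclusion sets genuinely admit no solution for
  some inputs — historically the same situation was resolved by a human
  relaxing a rule — and honest non-convergence, with the violation list
  attached, is the designed behaviour.
* Stems are exact-match; RNA secondary-structure energetics are out of
  scope, as are probabilistic splice-site models.
* The default motif set approximates the published exclusion classes, not
  a specific proprietary list; projects should supply their own.
* `global_identity()` uses a linear gap penalty; it exists as a fallback,
  not as a general-purpose aligner.
* The qPCR machinery starts from exported Ct values; raw fluorescence
  processing and Cq calling are upstream of this package.
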