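# recodon

Silencing-resistant transgene design by host-biased constrained reverse
translation, with the verification metrics and qPCR quantification math
that go with it.

## Who this is for

Anyone recoding a gene for a new host — typically a low-GC coding
sequence destined for a GC-rich plant such as sugarcane — who needs the
redesign to do more than "use preferred codons": the synthetic gene must
also be free of cryptic polyadenylation signals, AU-rich instability
elements, splice-site consensus motifs, A/T runs, direct repeats and
hairpin-forming inverted repeats, all of which can truncate, destabilise
or silence the transcript.  The motivating example is the recoding of the
firefly and *Renilla* luciferase reporters for sugarcane: GC raised from
45%/36.5% to 55%/52%, 75% nucleotide identity to the native genes, 100%
protein identity.

## What it computes

1. **Codon usage** — `build_usage_table()` from a host CDS FASTA, or
   `parse_kazusa_table()` for a Kazusa-style export;
   `filter_rare_codons()` drops codons below a relative synonymous
   frequency threshold (default 20%) and renormalises.
2. **Design** — `reverse_translate()` draws codons by seeded Monte Carlo
   from the filtered distribution; `screen()` locates every excluded
   feature (degenerate IUPAC motifs, A/T runs ≥ 6, direct repeats ≥ 10,
   palindromes ≥ 8, hairpin stems ≥ 12 bp, NotI/PacI sites, GC outside
   55 ± 3%); `repair()` iteratively resamples violating codons with
   GC-steered distributions until clean; `design()` wires it together
   with restarts; `finalize_construct()` adds tandem stops and unique
   cloning flanks.
3. **Verification** — `gc_content()`, `positional_identity()`,
   `global_identity()`, `codon_change_summary()`.
4. **qPCR math** — `design_discriminating_primers()` (transgene-specific
   pairs with 3'-anchored polymorphisms and equal amplicon lengths),
   `amplification_efficiency()` (E = (10^(−1/slope) − 1)·100),
   `comparative_ct_fold()` (fold = (1+E)^ΔCt), `relative_copy_number()`
   (2^−ΔΔCt).
5. **Synthetic data** — seeded generators (`random_protein()`,
   `synthetic_cds_set()`, `planted_screen_fixture()`,
   `native_like_cds()`, `simulate_ct_data()`) so the whole pipeline is
   testable offline with known ground truth.

## Worked example

```r
library(recodon)

# a synthetic GC-rich host corpus (71 CDS, coding average ~55.7% GC)
host <- build_usage_table(synthetic_cds_set(71, 300, gc3_bias = 0.8,
                                            seed = 42))

# a low-GC native-like gene carrying five excluded motifs
native <- native_like_cds(400, seed = 1)
gc_content(native)                       # 44.6
nrow(screen(native)$violations)          # 34

# redesign it
res <- design(native, host, seed = 7, max_rounds = 300)
res
#> Design result: 1161 nt, GC 55%, converged after 21 repair round(s)
#>   identity to native CDS: 76.6% (231 codons changed)
nrow(res$violations_remaining)           # 0
translate_cds(res$sequence) == translate_cds(native)  # TRUE

finalize_construct(res$sequence)         # NotI + ORF + TAA TGA + PacI
```

The redesigned gene keeps the protein exactly, lands inside the host GC
window, passes the full screen, and sits near 75% nucleotide identity to
its native counterpart — the same shape of result the motivating
luciferase redesigns report.

A command-line wrapper with subcommands (`usage-table`, `screen`,
`design`, `metrics`, `primers`, `qpcr-efficiency`, `qpcr-fold`,
`fixtures`) is installed at `inst/cli/recodon.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/recodon.R", package="recodon"))')" design --help
```

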