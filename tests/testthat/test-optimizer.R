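test_that("reverse translation is deterministic and honours fixed codons", {
  allowed <- filter_rare_codons(host_table(), 0.20)
  expect_equal(reverse_translate("M", allowed, seed = 1), "ATG")
  expect_equal(reverse_translate(strrep("W", 10), allowed, seed = 1),
               strrep("TGG", 10))
  p <- random_protein(80, seed = 2)
  expect_identical(reverse_translate(p, allowed, seed = 9),
                   reverse_translate(p, allowed, seed = 9))
  expect_error(reverse_translate("MX", allowed, seed = 1),
               "unencodable residue 'X' at position 2")
})

test_that("codon draws follow the allowed sampling distribution", {
  # two-codon alanine distribution, chi-square goodness of fit at n = 10000
  allowed <- structure(list(
    allowed = list(A = c(GCC = 0.6, GCG = 0.4)),
    threshold_used = 0.2), class = "allowed_codon_set")
  dna <- reverse_translate(strrep("A", 10000), allowed, seed = 31)
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  obs <- table(factor(codons, levels = c("GCC", "GCG")))
  p <- chisq.test(obs, p = c(0.6, 0.4))$p.value
  expect_gt(p, 0.01)
})

test_that("repair is a fixed point on an already-clean sequence", {
  cons <- design_constraints()
  allowed <- filter_rare_codons(host_table(), 0.20)
  # build a clean designed sequence first, then repair it again
  p <- random_protein(60, seed = 5)
  res0 <- design(p, host_table(), cons, seed = 5, max_rounds = 200,
                 restarts = 4)
  expect_true(res0$converged)
  res <- repair(res0$sequence, p, cons, allowed, seed = 1,
                max_rounds = 50)
  expect_identical(res$sequence, res0$sequence)
  expect_equal(res$rounds_used, 0)
  expect_true(res$converged)
})

test_that("repair removes a planted motif without touching the protein", {
  cons <- design_constraints()
  allowed <- filter_rare_codons(host_table(), 0.20)
  p <- random_protein(60, seed = 6)
  res0 <- design(p, host_table(), cons, seed = 6, max_rounds = 200,
                 restarts = 4)
  expect_true(res0$converged)
  # plant AATAAA by swapping in the Asn-Lys codons at a degenerate window
  codons <- substring(res0$sequence, seq(1, 180, 3), seq(3, 180, 3))
  prot <- strsplit(p, "")[[1]]
  prot[20:21] <- c("N", "K")
  codons[20:21] <- c("AAT", "AAA")
  dirty_protein <- paste(prot, collapse = "")
  dirty <- paste(codons, collapse = "")
  expect_gt(nrow(screen(dirty, cons)$violations), 0)
  res <- repair(dirty, dirty_protein, cons, allowed, seed = 11,
                max_rounds = 100)
  expect_true(res$converged)
  expect_equal(as.character(translate_cds(res$sequence)), dirty_protein)
  expect_equal(nrow(scan_motifs(res$sequence,
                                motif_pattern("AATAAA", "polyA"))), 0)
})

test_that("unsatisfiable constraints return the best effort, unconverged", {
  # poly-Lys protein: AAA/AAG only; banning A/T runs >= 2 is impossible
  cons <- design_constraints(min_at_run = 2, gc_target = 50,
                             gc_window = 49)
  allowed <- filter_rare_codons(host_table(), 0.20)
  p <- strrep("K", 20)
  dna <- reverse_translate(p, allowed, seed = 3)
  res <- repair(dna, p, cons, allowed, seed = 3, max_rounds = 20)
  expect_false(res$converged)
  expect_gt(nrow(res$violations_remaining), 0)
  expect_error(repair(dna, p, cons, allowed, seed = 3, max_rounds = 0),
               "max_rounds")
})

test_that("the best-so-far repair score never worsens across rounds", {
  cons <- design_constraints()
  allowed <- filter_rare_codons(host_table(), 0.20)
  p <- random_protein(100, seed = 8)
  dna <- reverse_translate(p, allowed, seed = 8)
  res <- repair(dna, p, cons, allowed, seed = 8, max_rounds = 100)
  h <- res$score_history
  if (nrow(h) > 1) {
    for (r in 2:nrow(h)) {
      expect_true(h[r, 1] < h[r - 1, 1] ||
                    (h[r, 1] == h[r - 1, 1] && h[r, 2] <= h[r - 1, 2]))
    }
  }
})

test_that("design round-trips the protein, converges, and is deterministic", {
  tab <- host_table()
  set.seed(99)
  for (i in 1:8) {
    p <- random_protein(sample(50:200, 1), seed = 300 + i)
    res <- design(p, tab, seed = i, max_rounds = 200, restarts = 4)
    expect_true(res$converged)
    expect_equal(nrow(res$violations_remaining), 0)
    expect_equal(as.character(translate_cds(res$sequence)), p)
    expect_lte(abs(res$metrics$gc_percent - 55), 3)
  }
  p <- random_protein(90, seed = 777)
  r1 <- design(p, tab, seed = 5, max_rounds = 200, restarts = 4)
  r2 <- design(p, tab, seed = 5, max_rounds = 200, restarts = 4)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$rounds_used, r2$rounds_used)
})

test_that("a low-GC native CDS is recoded up into the host GC window", {
  native <- native_like_cds(seed = 2)
  native_gc <- gc_content(native)
  expect_lt(native_gc, 55 - 3)
  res <- design(native, host_table(), seed = 17, max_rounds = 300,
                restarts = 4)
  expect_true(res$converged)
  expect_gt(res$metrics$gc_percent, native_gc)
  expect_lte(abs(res$metrics$gc_percent - 55), 3)
  # protein preserved, identity to the native CDS reported
  expect_equal(as.character(translate_cds(res$sequence)),
               as.character(translate_cds(native)))
  expect_true(res$metrics$identity_to_reference > 50 &&
                res$metrics$identity_to_reference < 100)
})

test_that("finalisation appends stops and unique flanking sites", {
  expect_equal(finalize_construct("ATGGCC"),
               "GCGGCCGCATGGCCTAATGATTAATTAA")
  expect_error(finalize_construct("ATGGCGGCCGCA"), "finalize error")
  expect_error(finalize_construct("ATGGCC", stop_codons = character(0)),
               "stop codon")
  expect_error(finalize_construct("ATGTAA"), "stop-free")
})
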