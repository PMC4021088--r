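test_that("motif scanning finds degenerate and overlapping occurrences", {
  v <- scan_motifs("GGGAATAAAGGG", motif_pattern("AATAAA", "polyA"))
  expect_equal(nrow(v), 1)
  expect_equal(c(v$start, v$end), c(4, 9))
  expect_equal(v$matched, "AATAAA")
  # degeneracy: R = A or G
  expect_equal(nrow(scan_motifs("ATTTA", motif_pattern("RTTTR", "x"))), 1)
  expect_equal(nrow(scan_motifs("GTTTG", motif_pattern("RTTTR", "x"))), 1)
  expect_equal(nrow(scan_motifs("CTTTC", motif_pattern("RTTTR", "x"))), 0)
  # self-overlapping pattern occurrences are all reported
  v2 <- scan_motifs("AAATAAATAAAT", motif_pattern("AAATAAAT", "ov"))
  expect_equal(v2$start, c(1, 5))
  expect_error(scan_motifs("ACGT", data.frame(label = "bad",
                                              category = "user",
                                              pattern = "AXGT")),
               "pattern-compile")
})

test_that("reverse-strand scanning reports forward coordinates", {
  # TTTAAC on the reverse strand of GTTAAA
  v <- scan_motifs("CCGTTAAACC", motif_pattern("TTTAAC", "x"),
                   both_strands = TRUE)
  expect_equal(nrow(v), 1)
  expect_equal(substr("CCGTTAAACC", v$start, v$end), v$matched)
})

test_that("A/T runs are maximal and mixed-base", {
  v <- find_at_runs("GGATATATAGG", 6)
  expect_equal(c(v$start, v$end, v$matched), c("3", "9", "ATATATA"))
  expect_equal(nrow(find_at_runs("GCGCGC", 6)), 0)
  v2 <- find_at_runs("AAAAAA", 6)
  expect_equal(c(v2$start, v2$end), c(1, 6))
})

test_that("planted direct repeats and hairpins are found, sub-threshold ones are not", {
  set.seed(42)
  # direct repeat: identical 10-mer planted twice in a random backbone
  unit <- "AAGGTTCCGG"
  mid <- random_dna(30, 0.6)
  seq <- paste0(unit, mid, unit, "C")
  v <- find_direct_repeats(seq, 10)
  expect_true(any(v$start == 1 & v$partner_start == 41))
  # hairpin: 12 bp arm + 4 nt loop + reverse complement arm
  arm <- "GACGTCCATGCA"
  hp <- paste0("CCG", arm, "TTTT",
               chartr("ACGT", "TGCA",
                      paste(rev(strsplit(arm, "")[[1]]), collapse = "")),
               "GCC")
  expect_equal(nrow(find_inverted_repeats(hp, 12)), 1)
  # 11 bp arms stay below a 12 bp stem threshold
  arm11 <- substr(arm, 1, 11)
  hp11 <- paste0("CCG", arm11, "TTTT",
                 chartr("ACGT", "TGCA",
                        paste(rev(strsplit(arm11, "")[[1]]), collapse = "")),
                 "GCC")
  expect_equal(nrow(find_inverted_repeats(hp11, 12)), 0)
  expect_equal(nrow(find_inverted_repeats(hp11, 11)), 1)
})

test_that("palindromes: textbook site found, A-run is not a palindrome", {
  v <- find_palindromes("GAATTC", 6)
  expect_equal(c(v$start, v$end), c(1, 6))
  expect_equal(nrow(find_palindromes("AAAAAAAA", 8)), 0)
  expect_error(find_palindromes("ACGT", 7), "even")
})

test_that("every scanner matches its brute-force oracle on random sequences", {
  set.seed(123)
  motifs <- default_motif_set()
  for (rep in 1:30) {
    seq <- random_dna(300, gc = sample(c(0.4, 0.5, 0.6), 1))
    # motifs
    v <- scan_motifs(seq, motifs)
    got <- sort(paste(v$label, v$start))
    want <- sort(unlist(lapply(seq_len(nrow(motifs)), function(i) {
      h <- oracle_scan_motif(seq, motifs$pattern[i])
      if (length(h)) paste(motifs$label[i], h) else character(0)
    })))
    expect_identical(got, want)
    # A/T runs
    expect_identical(sort_rows(viol_spans(find_at_runs(seq, 6))),
                     sort_rows(oracle_at_runs(seq, 6)))
    # direct repeats (threshold 8 so random hits actually occur)
    expect_identical(sort_rows(viol_pairs(find_direct_repeats(seq, 8))),
                     sort_rows(oracle_direct_repeats(seq, 8)))
    # inverted repeats at a stem of 8 for the same reason
    expect_identical(sort_rows(viol_pairs(find_inverted_repeats(seq, 8))),
                     sort_rows(oracle_inverted_repeats(seq, 8)))
    # palindromes
    expect_identical(sort_rows(viol_spans(find_palindromes(seq, 8))),
                     sort_rows(oracle_palindromes(seq, 8)))
  }
})

test_that("violations stay in bounds and match their sequence slice", {
  set.seed(7)
  cons <- design_constraints(min_direct_repeat = 8, min_stem = 8,
                             gc_target = 50)
  for (rep in 1:10) {
    seq <- random_dna(400)
    v <- screen(seq, cons)$violations
    v <- v[v$kind != "gc_window", , drop = FALSE]
    if (nrow(v) == 0) next
    expect_true(all(v$start >= 1 & v$end <= nchar(seq) & v$start <= v$end))
    expect_identical(substring(seq, v$start, v$end), v$matched)
  }
})

test_that("palindrome hits are a subset of inverted-repeat hits at matched thresholds", {
  set.seed(11)
  for (rep in 1:10) {
    seq <- random_dna(300, 0.6)
    pal <- find_palindromes(seq, 8)
    ir <- find_inverted_repeats(seq, 4)
    if (nrow(pal) == 0) next
    # each palindrome is a zero-loop inverted repeat: its arms appear as
    # an IR pair with contiguous arms covering the same span
    for (k in seq_len(nrow(pal))) {
      covered <- any(ir$start <= pal$start[k] & ir$partner_end >= pal$end[k] &
                       ir$partner_start == ir$end + 1)
      expect_true(covered)
    }
  }
})

test_that("palindrome and inverted-repeat counts are strand-symmetric", {
  set.seed(13)
  for (rep in 1:10) {
    seq <- random_dna(300, 0.6)
    rc <- reverse_complement(seq)
    expect_equal(nrow(find_palindromes(rc, 8)),
                 nrow(find_palindromes(seq, 8)))
    expect_equal(nrow(find_inverted_repeats(rc, 8)),
                 nrow(find_inverted_repeats(seq, 8)))
  }
})

test_that("screen unions all finders and flags GC breaches", {
  cons <- design_constraints(gc_target = 55, gc_window = 3)
  fix <- planted_screen_fixture(
    300, list(list(kind = "motif", payload = "AATAAA", position = 50),
              list(kind = "hairpin", payload = c(12, 4), position = 150)),
    cons, seed = 4)
  kinds <- fix$report$violations$kind
  expect_setequal(unique(kinds), c("motif", "at_run", "inverted_repeat"))
  # low-GC sequence against a 55% target: gc_window violation present
  set.seed(3)
  low <- random_dna(300, gc = 0.45)
  rep_low <- screen(low, design_constraints(min_direct_repeat = 8,
                                            gc_target = 55, gc_window = 3))
  expect_false(rep_low$gc_ok)
  expect_true("gc_window" %in% rep_low$violations$kind)
  # clean sequence with matched target: empty report
  clean <- random_clean_dna(200, cons, seed = 9)
  expect_equal(nrow(screen(clean, cons)$violations), 0)
})
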