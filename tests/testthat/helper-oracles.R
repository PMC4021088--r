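# Independent brute-force oracles for the feature scanners.  These share
# no code with the package scanners: seed discovery is direct enumeration
# and maximality is checked against the definition.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# every (overlapping) occurrence of one IUPAC pattern: position-by-position
# set membership
oracle_scan_motif <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(s); m <- length(p)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1)
  for (k in 1:m) {
    ok <- ok & (s[k:(n - m + k)] %in% iupac_sets[[p[k]]])
  }
  which(ok)
}

oracle_at_runs <- function(seq, min_run) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  at <- s %in% c("A", "T")
  r <- rle(at)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  cbind(start = starts[keep], end = ends[keep])
}

# all maximal direct-repeat pairs: enumerate every seed pair directly,
# extend left then right under the no-collision rule, then dedupe
oracle_direct_repeats <- function(seq, min_len) {
  n <- nchar(seq); L <- min_len
  if (n < 2 * L) return(matrix(integer(0), ncol = 4))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  w <- substring(seq, 1:(n - L + 1), L:n)
  out <- matrix(integer(0), ncol = 4)
  for (i in seq_along(w)) {
    js <- which(w == w[i])
    for (j in js[js >= i + L]) {
      s1 <- i; e1 <- i + L - 1; s2 <- j; e2 <- j + L - 1
      while (s1 > 1 && s2 - 1 > e1 && ch[s1 - 1] == ch[s2 - 1]) {
        s1 <- s1 - 1; s2 <- s2 - 1
      }
      while (e2 < n && e1 + 1 < s2 && ch[e1 + 1] == ch[e2 + 1]) {
        e1 <- e1 + 1; e2 <- e2 + 1
      }
      out <- rbind(out, c(s1, e1, s2, e2))
    }
  }
  unique(out)
}

# all maximal inverted-repeat pairs: direct pairwise arm comparison
oracle_inverted_repeats <- function(seq, min_stem) {
  n <- nchar(seq); L <- min_stem
  if (n < 2 * L) return(matrix(integer(0), ncol = 4))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- substring(seq, 1:(n - L + 1), L:n)
  out <- matrix(integer(0), ncol = 4)
  for (i in seq_along(w)) {
    rc <- oracle_revcomp(w[i])
    js <- which(w == rc)
    for (j in js[js >= i + L]) {
      s1 <- i; e1 <- i + L - 1; s2 <- j; e2 <- j + L - 1
      while (s1 > 1 && e2 < n && ch[s1 - 1] == comp[[ch[e2 + 1]]]) {
        s1 <- s1 - 1; e2 <- e2 + 1
      }
      while (e1 + 1 < s2 - 1 && ch[e1 + 1] == comp[[ch[s2 - 1]]]) {
        e1 <- e1 + 1; s2 <- s2 - 1
      }
      out <- rbind(out, c(s1, e1, s2, e2))
    }
  }
  unique(out)
}

# all maximal even palindromes by exhaustive substring testing up to
# max_len (maximality = the one-step outward extension is not palindromic).
# Uses the identity revcomp(seq[s..e]) == revcomp(seq)[n-e+1 .. n-s+1].
oracle_palindromes <- function(seq, min_len, max_len = 30) {
  n <- nchar(seq)
  rc <- oracle_revcomp(seq)
  is_pal <- function(s, e) {
    inb <- s >= 1 & e <= n
    out <- rep(FALSE, length(s))
    out[inb] <- substring(seq, s[inb], e[inb]) ==
      substring(rc, n - e[inb] + 1, n - s[inb] + 1)
    out
  }
  out <- matrix(integer(0), ncol = 2)
  for (len in seq(min_len, min(n, max_len), by = 2)) {
    s <- 1:(n - len + 1)
    e <- s + len - 1
    keep <- is_pal(s, e) & !is_pal(s - 1, e + 1)
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  unique(out)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# violation data frame -> comparable matrices
viol_pairs <- function(v) {
  if (nrow(v) == 0) return(matrix(integer(0), ncol = 4))
  unique(cbind(v$start, v$end, v$partner_start, v$partner_end))
}
viol_spans <- function(v) {
  if (nrow(v) == 0) return(matrix(integer(0), ncol = 2))
  unique(cbind(v$start, v$end))
}

sort_rows <- function(m) {
  m <- unname(as.matrix(m))
  storage.mode(m) <- "double"
  if (nrow(m) == 0) return(m)
  m[do.call(order, split(m, col(m))), , drop = FALSE]
}
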