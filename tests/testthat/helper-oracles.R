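# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: edit distance is a hand-rolled
# DP, the tiling oracles work top-down over suffixes (the package DP is
# bottom-up over prefix ends), the motif checker tests membership
# position by position via Biostrings::IUPAC_CODE_MAP, and the alignment
# oracle enumerates complete op-strings.

# plain Levenshtein distance, quadratic DP
lev <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  d[n + 1L, m + 1L]
}

seg_cost <- function(seg, consensus, penalty) {
  lev(seg, consensus) + penalty * abs(nchar(seg) - 5L)
}

# minimum tiling cost by memoised top-down recursion over suffixes
oracle_tiling_cost <- function(seq, consensus = "TTCCA", lens = 3:7,
                               penalty = 0) {
  n <- nchar(seq)
  memo <- rep(NA_real_, n + 1L)
  rec <- function(pos) {  # min cost of tiling seq[pos..n]; pos in 1..n+1
    if (pos == n + 1L) return(0)
    if (!is.na(memo[pos])) return(memo[pos])
    best <- Inf
    for (L in lens) {
      if (pos + L - 1L <= n) {
        c0 <- seg_cost(substr(seq, pos, pos + L - 1L), consensus, penalty)
        best <- min(best, c0 + rec(pos + L))
      }
    }
    memo[pos] <<- best
    best
  }
  rec(1L)
}

# exhaustive enumeration of every tiling (small n only)
oracle_tiling_enumerate <- function(seq, consensus = "TTCCA", lens = 3:7,
                                    penalty = 0) {
  n <- nchar(seq)
  best <- Inf
  rec <- function(pos, acc) {
    if (pos == n + 1L) { best <<- min(best, acc); return(invisible()) }
    for (L in lens) {
      if (pos + L - 1L <= n)
        rec(pos + L,
            acc + seg_cost(substr(seq, pos, pos + L - 1L), consensus, penalty))
    }
  }
  rec(1L, 0)
  best
}

# naive position-by-position degenerate motif scan (forward strand)
naive_scan_starts <- function(seq, recog) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(recog, "")[[1]]], "")
  s <- strsplit(seq, "")[[1]]
  k <- length(sets); n <- length(s)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (start in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (off in seq_len(k)) {
      if (!(s[start + off - 1L] %in% sets[[off]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# affine-gap score of one explicit op-string
score_ops <- function(ops, a, b, p) {
  i <- 0L; j <- 0L; sc <- 0; prev <- ""
  for (op in ops) {
    if (op == "D") {          # diagonal
      i <- i + 1L; j <- j + 1L
      sc <- sc + if (substr(a, i, i) == substr(b, j, j)) p$match else p$mismatch
    } else if (op == "X") {   # gap in b, consumes a
      i <- i + 1L
      sc <- sc + if (prev == "X") p$gap_extend else p$gap_open
    } else {                  # "Y": gap in a, consumes b
      j <- j + 1L
      sc <- sc + if (prev == "Y") p$gap_extend else p$gap_open
    }
    prev <- op
  }
  sc
}

# exhaustive enumeration of all global alignments (tiny inputs only)
oracle_align_enumerate <- function(a, b, p = alignment_params()) {
  n <- nchar(a); m <- nchar(b)
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i == n && j == m) {
      best <<- max(best, score_ops(ops, a, b, p))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(ops, "D"))
    if (i < n) rec(i + 1L, j, c(ops, "X"))
    if (j < m) rec(i, j + 1L, c(ops, "Y"))
  }
  rec(0L, 0L, character(0))
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# TTCCA-biased random sequence: pentamer units with occasional noise,
# closer to real array composition than uniform random
random_arrayish <- function(units, noise = 0.1) {
  u <- replicate(units, {
    s <- strsplit("TTCCA", "")[[1]]
    flip <- runif(5) < noise
    s[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    paste(s, collapse = "")
  })
  paste(u, collapse = "")
}
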