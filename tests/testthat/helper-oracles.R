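# Independent oracles used by the property-style tests. These
# deliberately re-derive results through different code paths than the
# package implementation.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Brute-force codon walk: tests every position of the transcript as a
# potential start, independent of extend_orf's vectorized scan.
oracle_extend <- function(seq, start) {
  p <- start
  n_codons <- 0L
  repeat {
    if (p + 2L > nchar(seq)) return(NULL)
    codon <- substr(seq, p, p + 2L)
    if (codon %in% c("UAA", "UAG", "UGA")) {
      return(list(start = start, stop_end = p + 2L, len_codons = n_codons))
    }
    n_codons <- n_codons + 1L
    p <- p + 3L
  }
}

# Brute-force enumeration of internal out-of-frame AUG-initiated short
# ORFs: every position is tested explicitly.
oracle_sorfs <- function(seq, ctis, max_codons = 100L) {
  out <- list()
  for (p in seq_len(nchar(seq) - 2L)) {
    if (p <= ctis) next
    if ((p - ctis) %% 3L == 0L) next
    if (substr(seq, p, p + 2L) != "AUG") next
    orf <- oracle_extend(seq, p)
    if (is.null(orf) || orf$len_codons > max_codons) next
    out[[length(out) + 1L]] <- orf
  }
  out
}

# Plain memoized recursion for the global alignment score (match +1,
# mismatch -1, linear gap -2); score is unique even when the optimal
# alignment is not.
oracle_nw_score <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- matrix(NA_real_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    val <- if (i == 0L && j == 0L) 0
    else if (i == 0L) -2 * j
    else if (j == 0L) -2 * i
    else max(rec(i - 1L, j - 1L) + (if (av[i] == bv[j]) 1 else -1),
             rec(i - 1L, j) - 2,
             rec(i, j - 1L) - 2)
    memo[i + 1L, j + 1L] <<- val
    val
  }
  rec(n, m)
}

# Benjamini-Hochberg from its definition: adjusted p(i) (in sorted
# order) is min over j >= i of (m / j) * p(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min((m / seq(i, m)) * sorted[seq(i, m)]))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Re-checks every candidate a screen emits against the raw sequence.
expect_candidates_valid <- function(candidates, transcripts,
                                    params = screen_params()) {
  for (i in seq_len(nrow(candidates))) {
    seq <- transcripts$seq[transcripts$id == candidates$transcript_id[i]]
    expect_true(isTRUE(validate_candidate(candidates[i, ], seq, params)),
                label = sprintf("candidate %d re-passes all filters", i))
  }
}
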