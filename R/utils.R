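#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All generators in this package draw their randomness through
# this helper, so nothing depends on (or mutates) global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")
TIS_CODONS <- c("AUG", "CUG", "GUG", "ACG", "AUA", "AUU", "AUC", "UUG")

codon_at <- function(seq, pos) substr(seq, pos, pos + 2L)

# All overlapping start positions of a fixed trinucleotide; a trinucleotide
# cannot overlap itself at period 1 or 2, so non-overlapping search suffices
# for AUG but not in general -- scan all frames explicitly.
find_triplet <- function(seq, triplet) {
  n <- nchar(seq)
  if (n < 3L) return(integer(0))
  starts <- seq_len(n - 2L)
  starts[substring(seq, starts, starts + 2L) == triplet]
}

find_stop_positions <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(integer(0))
  starts <- seq_len(n - 2L)
  starts[substring(seq, starts, starts + 2L) %in% STOP_CODONS]
}
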