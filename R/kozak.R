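# Kozak-context extraction and classification.
#
# The consensus for efficient initiation is RNN RNN AUG G (R = purine):
# the residues that matter most are the purine at -3 and the G at +4,
# and GCCACC-AUG-G is the textbook "perfect" context. The package
# formalizes the field's informal labels into four tiers:
#
#   optimal   -6..-1 == GCCACC and +4 == G (the "perfect" context)
#   strong    purine at -3 AND G at +4 (but not optimal)
#   adequate  exactly one of {purine at -3, G at +4} (e.g. CCC AUG G)
#   weak      neither (e.g. U at -3 and U at +4)
#
# plus "indeterminate" when -3 or +4 is missing (window off the 5'/3'
# end) or is an N. The tier depends only on the window.

KOZAK_TIERS <- c("optimal", "strong", "adequate", "weak", "indeterminate")

#' Extract the Kozak context window around a start codon
#'
#' The window covers positions -6..-1, the start codon (+1..+3) and +4,
#' i.e. 10 residues when fully inside the transcript. Windows running
#' off the 5' end are built from the available residues; the tier is
#' then computed only if both -3 and +4 exist.
#'
#' @param seq RNA sequence string.
#' @param tis_pos 1-based position of the start codon's first nucleotide.
#' @return Object of class `kozak_context`: list with `window`,
#'   `minus3`, `plus4`, `tier`, `pos`.
#' @export
kozak_context <- function(seq, tis_pos) {
  n <- nchar(seq)
  if (!is_count(tis_pos, 1L) || tis_pos + 2L > n) {
    abort("tis_pos %s out of bounds for transcript of length %d",
          format(tis_pos), n)
  }
  lo <- max(1L, tis_pos - 6L)
  hi <- min(n, tis_pos + 3L)
  window <- substr(seq, lo, hi)
  minus3 <- if (tis_pos - 3L >= 1L) substr(seq, tis_pos - 3L, tis_pos - 3L)
            else NA_character_
  plus4 <- if (tis_pos + 3L <= n) substr(seq, tis_pos + 3L, tis_pos + 3L)
           else NA_character_
  full <- tis_pos - 6L >= 1L && tis_pos + 3L <= n
  ctx <- structure(list(window = window, minus3 = minus3, plus4 = plus4,
                        pos = as.integer(tis_pos), full_window = full,
                        tier = NA_character_),
                   class = "kozak_context")
  ctx$tier <- classify_kozak(ctx)
  ctx
}

#' Classify a Kozak context into a tier
#'
#' Pure, total function of the window; see the tier definitions in the
#' package documentation. Accepts either a `kozak_context` or a raw
#' 10-residue window string (-6..+4).
#'
#' @param ctx A `kozak_context` or a character window.
#' @return One of `"optimal"`, `"strong"`, `"adequate"`, `"weak"`,
#'   `"indeterminate"`.
#' @examples
#' classify_kozak("GCCACCAUGG") # optimal
#' classify_kozak("CUUUUUAUGU") # weak
#' @export
classify_kozak <- function(ctx) {
  if (is.character(ctx)) {
    if (nchar(ctx) != 10L) abort("raw window must have 10 residues (-6..+4)")
    ctx <- list(window = ctx,
                minus3 = substr(ctx, 4L, 4L),
                plus4 = substr(ctx, 10L, 10L),
                full_window = TRUE)
  }
  m3 <- ctx$minus3
  p4 <- ctx$plus4
  if (is.na(m3) || is.na(p4) || m3 == "N" || p4 == "N") return("indeterminate")
  purine_m3 <- m3 %in% c("A", "G")
  g_p4 <- p4 == "G"
  if (isTRUE(ctx$full_window) && substr(ctx$window, 1L, 6L) == "GCCACC" && g_p4) {
    return("optimal")
  }
  if (purine_m3 && g_p4) return("strong")
  if (purine_m3 || g_p4) return("adequate")
  "weak"
}

#' @export
print.kozak_context <- function(x, ...) {
  cat(sprintf("Kozak context at %d: %s (-3 = %s, +4 = %s) -> %s\n",
              x$pos, x$window, x$minus3, x$plus4, x$tier))
  invisible(x)
}
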