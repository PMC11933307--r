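# Frame arithmetic and ORF enumeration relative to the canonical TIS.
#
# Everything is expressed in the coordinate frame of the mature mRNA
# (1-based inclusive). "Frame" is the offset (pos - cTIS) mod 3, so 0
# means in-frame with the canonical ORF.

#' Reading-frame offset of a position relative to the canonical TIS
#'
#' @param pos 1-based position (vectorized).
#' @param ctis 1-based position of the canonical start codon.
#' @return Integer offset(s) in `{0, 1, 2}`; 0 means in-frame.
#' @examples
#' frame_offset(480, 480) # 0
#' frame_offset(359, 480) # 1: out of frame
#' @export
frame_offset <- function(pos, ctis) {
  stopifnot(all(pos >= 1L), all(ctis >= 1L))
  as.integer((pos - ctis) %% 3L)
}

#' Canonical ORF descriptor
#'
#' @param transcript_id Transcript identifier.
#' @param ctis 1-based position of the canonical start codon.
#' @param cstop_end 1-based position of the last nucleotide of the
#'   canonical stop codon.
#' @return An object of class `canonical_orf`.
#' @export
canonical_orf <- function(transcript_id, ctis, cstop_end) {
  if (!is_count(ctis, 1L) || !is_count(cstop_end, 1L)) {
    abort("ctis and cstop_end must be positive integers")
  }
  if (cstop_end <= ctis) abort("cstop_end must be > ctis")
  if ((cstop_end - ctis + 1L) %% 3L != 0L) {
    abort("canonical ORF length (%d nt) is not a multiple of 3",
          cstop_end - ctis + 1L)
  }
  structure(list(transcript_id = transcript_id, ctis = as.integer(ctis),
                 cstop_end = as.integer(cstop_end)),
            class = "canonical_orf")
}

#' Extend an ORF from a start position to its first in-frame stop
#'
#' Walks codon-by-codon from `start`; the interval ends at the first
#' in-frame stop codon. ORFs that run off the 3' end without a stop are
#' discarded (`NULL`), not truncated.
#'
#' @param seq RNA sequence string (internal alphabet).
#' @param start 1-based position of the start codon.
#' @param transcript_id Identifier recorded in the result.
#' @param ctis Optional canonical TIS used to annotate the frame.
#' @param init_score Optional initiation score carried through.
#' @return One-row `data.frame` (`transcript_id`, `start`, `stop_end`,
#'   `len_codons`, `frame`, `start_codon`, `init_score`) or `NULL` when
#'   no in-frame stop exists. `len_codons` counts coding codons and
#'   excludes the stop codon.
#' @export
extend_orf <- function(seq, start, transcript_id = "transcript",
                       ctis = NA_integer_, init_score = NA_real_) {
  n <- nchar(seq)
  if (!is_count(start, 1L) || start + 2L > n) {
    abort("start %s out of bounds for transcript of length %d",
          format(start), n)
  }
  start <- as.integer(start)
  codon_starts <- seq.int(start, n - 2L, by = 3L)
  codons <- substring(seq, codon_starts, codon_starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) return(NULL)
  stop_start <- codon_starts[hit[1L]]
  data.frame(
    transcript_id = transcript_id,
    start = start,
    stop_end = as.integer(stop_start + 2L),
    len_codons = as.integer(hit[1L] - 1L),
    frame = if (is.na(ctis)) NA_integer_ else frame_offset(start, ctis),
    start_codon = codon_at(seq, start),
    init_score = init_score,
    stringsAsFactors = FALSE)
}

empty_orf_intervals <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             stop_end = integer(0), len_codons = integer(0),
             frame = integer(0), start_codon = character(0),
             init_score = numeric(0), stringsAsFactors = FALSE)
}

#' Enumerate internal out-of-frame short ORFs
#'
#' Candidate starts are either the supplied TIS calls (positions 3' of
#' the canonical TIS with a non-zero frame offset) or, in de-novo mode
#' (`tis_calls = NULL`), every AUG matching those positional filters.
#' Near-cognate starts (CUG, ACG, ...) are admitted only through explicit
#' TIS calls; de-novo near-cognate scanning would flood the screen.
#' Each start is extended to its first in-frame stop; ORFs longer than
#' `max_codons` coding codons or lacking a stop are discarded.
#'
#' @param seq RNA sequence string.
#' @param canonical A [canonical_orf()].
#' @param tis_calls `data.frame` of TIS calls for this transcript
#'   (columns `pos`, `codon`, `init_score`), or `NULL` for de-novo AUG
#'   discovery.
#' @param max_codons Length cap in coding codons (default 100, the
#'   screen's "short ORF" definition).
#' @param start_codons De-novo start codons (default `"AUG"`).
#' @return `data.frame` of ORF intervals sorted by `start`.
#' @export
enumerate_internal_sorfs <- function(seq, canonical, tis_calls = NULL,
                                     max_codons = 100L,
                                     start_codons = "AUG") {
  if (!inherits(canonical, "canonical_orf")) abort("canonical ORF is required")
  if (!is_count(max_codons, 1L)) abort("max_codons must be >= 1")
  ctis <- canonical$ctis
  if (is.null(tis_calls)) {
    starts <- sort(unlist(lapply(start_codons, find_triplet, seq = seq),
                          use.names = FALSE))
    scores <- rep(NA_real_, length(starts))
  } else {
    starts <- as.integer(tis_calls$pos)
    scores <- as.numeric(tis_calls$init_score)
  }
  keep <- starts > ctis & frame_offset(pmax(starts, 1L), ctis) != 0L &
    starts + 2L <= nchar(seq)
  starts <- starts[keep]
  scores <- scores[keep]
  if (!length(starts)) return(empty_orf_intervals())
  rows <- lapply(seq_along(starts), function(i) {
    orf <- extend_orf(seq, starts[i], canonical$transcript_id,
                      ctis = ctis, init_score = scores[i])
    if (is.null(orf) || orf$len_codons > max_codons) NULL else orf
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_orf_intervals())
  out <- out[!duplicated(out$start), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Internal in-frame TIS calls for truncated proteoforms
#'
#' Keeps calls strictly inside the canonical ORF (`cTIS < pos <
#' cSTOP_end - 2`) with frame offset 0. The call's stated codon is kept
#' as-is: near-cognate internal starts enter only through the TIS table.
#'
#' @inheritParams enumerate_internal_sorfs
#' @param tis_calls `data.frame` of TIS calls (columns `pos`, `codon`,
#'   `init_score`, optionally `is_canonical`).
#' @return Filtered `data.frame` of calls sorted by `pos`.
#' @export
enumerate_inframe_tis <- function(seq, canonical, tis_calls) {
  if (!inherits(canonical, "canonical_orf")) abort("canonical ORF is required")
  if (is.null(tis_calls)) {
    return(data.frame(pos = integer(0), codon = character(0),
                      init_score = numeric(0), stringsAsFactors = FALSE))
  }
  if (nrow(tis_calls) == 0L) return(tis_calls)
  keep <- frame_offset(pmax(tis_calls$pos, 1L), canonical$ctis) == 0L &
    tis_calls$pos > canonical$ctis &
    tis_calls$pos < canonical$cstop_end - 2L
  out <- tis_calls[keep, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

#' Next in-frame start codon at or after a position
#'
#' @inheritParams enumerate_internal_sorfs
#' @param from_pos 1-based search origin (inclusive).
#' @param start_codons Codons accepted as starts (default `"AUG"`).
#' @return Smallest in-frame position `>= from_pos` whose codon is in
#'   `start_codons` and which lies 5' of the canonical stop codon, or
#'   `NA_integer_` when none exists.
#' @export
next_inframe_start <- function(seq, canonical, from_pos,
                               start_codons = "AUG") {
  if (!inherits(canonical, "canonical_orf")) abort("canonical ORF is required")
  if (from_pos < canonical$ctis) abort("from_pos must be >= cTIS")
  limit <- canonical$cstop_end - 2L
  pos <- from_pos + ((canonical$ctis - from_pos) %% 3L)
  if (pos >= limit) return(NA_integer_)
  candidates <- seq.int(pos, limit - 1L, by = 3L)
  candidates <- candidates[candidates + 2L <= nchar(seq)]
  hits <- candidates[substring(seq, candidates, candidates + 2L) %in% start_codons]
  if (!length(hits)) NA_integer_ else hits[1L]
}

# Derive the canonical ORF by extending from an annotated CDS start.
derive_canonical <- function(seq, ctis, transcript_id = "transcript") {
  orf <- extend_orf(seq, ctis, transcript_id)
  if (is.null(orf)) {
    abort("transcript '%s': no in-frame stop downstream of cTIS %d",
          transcript_id, ctis)
  }
  canonical_orf(transcript_id, ctis, orf$stop_end)
}

# Type-invariant validator used by tests and by the synthetic-data
# certificate.
validate_orf_interval <- function(orf, seq = NULL, ctis = NULL) {
  if (nrow(orf) == 0L) return(TRUE)
  ok <- (orf$stop_end - orf$start + 1L) %% 3L == 0L &
    orf$len_codons == (orf$stop_end - orf$start + 1L) %/% 3L - 1L
  if (!is.null(ctis)) ok <- ok & orf$frame == frame_offset(orf$start, ctis)
  if (!is.null(seq)) {
    ok <- ok & substring(seq, orf$stop_end - 2L, orf$stop_end) %in% STOP_CODONS &
      substring(seq, orf$start, orf$start + 2L) == orf$start_codon
  }
  all(ok)
}
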