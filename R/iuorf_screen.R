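# The candidate-identification screen: pair internal out-of-frame short
# ORFs (iuORFs) with internal in-frame TISs for N-terminally truncated
# proteoforms (ntTIS), apply positional filters, tie-break, and classify
# the geometry as upstream or overlapping.
#
# Geometry, all 1-based on the mRNA:
#
#   upstream:     cTIS ... iuTIS ---- iuSTOP ..spacer.. ntTIS ... cSTOP
#   overlapping:  cTIS ... iuTIS ---- ntTIS ---- iuSTOP ....... cSTOP
#
# spacer_nt = ntTIS - iuSTOP_end (positive when the stop lies strictly
# 5' of the ntTIS). "Upstream" requires 1 <= spacer <= 30 nt by default;
# "overlapping" requires iuSTOP_end > ntTIS.

#' Screen parameters
#'
#' Defaults mirror the published filter: short ORFs of at most 100
#' coding codons, upstream stop at most 30 nt 5' of the
#' truncated-proteoform TIS.
#'
#' @param max_codons Maximum iuORF length in coding codons (stop
#'   excluded).
#' @param max_upstream_spacer_nt Maximum spacer for the upstream class.
#' @param start_codons_denovo Codons used for de-novo start discovery.
#' @param mode `"tis-calls"` (starts come from the TIS table) or
#'   `"de-novo"` (every AUG is considered and initiation scores are
#'   unavailable).
#' @return Object of class `screen_params`.
#' @export
screen_params <- function(max_codons = 100L, max_upstream_spacer_nt = 30L,
                          start_codons_denovo = "AUG",
                          mode = c("tis-calls", "de-novo")) {
  mode <- match.arg(mode)
  if (!is_count(max_codons, 1L)) abort("max_codons must be >= 1")
  if (!is_count(max_upstream_spacer_nt, 0L)) {
    abort("max_upstream_spacer_nt must be >= 0")
  }
  structure(list(max_codons = as.integer(max_codons),
                 max_upstream_spacer_nt = as.integer(max_upstream_spacer_nt),
                 start_codons_denovo = start_codons_denovo,
                 mode = mode),
            class = "screen_params")
}

#' Spacer between an iuORF stop codon and a downstream TIS
#'
#' @param iustop_end 1-based position of the stop codon's last
#'   nucleotide.
#' @param nttis 1-based position of the downstream TIS.
#' @return Signed integer `nttis - iustop_end`; positive when the stop
#'   ends strictly 5' of the TIS, negative in overlap geometry.
#' @examples
#' spacer_nt(466, 480) # 14, the Trip6-like wild-type geometry
#' @export
spacer_nt <- function(iustop_end, nttis) {
  stopifnot(all(iustop_end >= 1L), all(nttis >= 1L))
  as.integer(nttis - iustop_end)
}

#' Pair a short ORF with its nearest qualifying downstream TIS
#'
#' For each internal in-frame TIS 3' of the sORF start: the pair is
#' "overlapping" when the sORF stop ends 3' of the TIS, "upstream" when
#' `1 <= spacer <= max_upstream_spacer_nt`, otherwise it does not
#' qualify. Only the nearest qualifying TIS (smallest `ntTIS - iuTIS`)
#' is kept.
#'
#' @param sorf One-row ORF interval (see [extend_orf()]).
#' @param nt_calls `data.frame` of internal in-frame TIS calls
#'   (columns `pos`, `codon`).
#' @param params [screen_params()].
#' @param ctis Canonical TIS position (recorded in the candidate).
#' @return Candidate `data.frame` with 0 or 1 row; Kozak tiers are not
#'   yet attached (see [screen_transcript()]).
#' @export
pair_and_classify <- function(sorf, nt_calls, params = screen_params(),
                              ctis = NA_integer_) {
  stopifnot(is.data.frame(sorf), nrow(sorf) == 1L)
  if (is.null(nt_calls) || nrow(nt_calls) == 0L) return(empty_candidates())
  nt <- nt_calls[nt_calls$pos > sorf$start, , drop = FALSE]
  if (!nrow(nt)) return(empty_candidates())
  sp <- spacer_nt(sorf$stop_end, nt$pos)
  klass <- ifelse(sorf$stop_end > nt$pos, "overlapping",
                  ifelse(sp >= 1L & sp <= params$max_upstream_spacer_nt,
                         "upstream", NA_character_))
  ok <- which(!is.na(klass))
  if (!length(ok)) return(empty_candidates())
  best <- ok[which.min(nt$pos[ok] - sorf$start)]
  data.frame(
    transcript_id = sorf$transcript_id,
    cTIS = as.integer(ctis),
    iuTIS = sorf$start,
    iuSTOP_end = sorf$stop_end,
    ntTIS = as.integer(nt$pos[best]),
    class = klass[best],
    spacer_nt = sp[best],
    iuORF_len_codons = sorf$len_codons,
    iu_kozak = NA_character_,
    nt_kozak = NA_character_,
    init_score = sorf$init_score,
    stringsAsFactors = FALSE)
}

# In de-novo mode, fabricate TIS-like calls for every AUG so the same
# pairing code serves both modes. Scores are unavailable de novo.
denovo_calls <- function(seq, start_codons = "AUG") {
  pos <- sort(unlist(lapply(start_codons, find_triplet, seq = seq),
                     use.names = FALSE))
  data.frame(pos = as.integer(pos),
             codon = substring(seq, pos, pos + 2L),
             init_score = NA_real_,
             is_canonical = FALSE,
             stringsAsFactors = FALSE)
}

#' Screen one transcript for an iuORF candidate
#'
#' Enumerates internal out-of-frame short ORFs and internal in-frame
#' TISs, pairs and classifies them, and keeps at most one candidate:
#' the short ORF with the highest initiation score; ties are broken by
#' smaller absolute spacer, then by the 5'-most iuTIS. When scores are
#' absent (de-novo mode) the tie-break starts at the spacer. Kozak tiers
#' are attached for both the iuTIS and the ntTIS.
#'
#' @param seq RNA sequence string.
#' @param tis_calls TIS calls for this transcript (the canonical call
#'   must be flagged), or `NULL` in de-novo mode with `ctis` supplied.
#' @param params [screen_params()].
#' @param transcript_id Identifier for the transcript.
#' @param ctis Canonical TIS position; defaults to the flagged canonical
#'   call in `tis_calls`.
#' @return Candidate `data.frame` with 0 or 1 row.
#' @export
screen_transcript <- function(seq, tis_calls = NULL,
                              params = screen_params(),
                              transcript_id = "transcript",
                              ctis = NULL) {
  if (is.null(ctis)) {
    if (is.null(tis_calls)) abort("either tis_calls or ctis is required")
    canon_rows <- which(tis_calls$is_canonical)
    if (length(canon_rows) > 1L) {
      abort("transcript '%s': multiple canonical TIS calls", transcript_id)
    }
    if (!length(canon_rows)) return(empty_candidates())
    ctis <- tis_calls$pos[canon_rows]
  }
  if (codon_at(seq, ctis) %in% STOP_CODONS) {
    abort("transcript '%s': cTIS %d is a stop codon", transcript_id, ctis)
  }
  canonical <- tryCatch(derive_canonical(seq, ctis, transcript_id),
                        error = function(e) NULL)
  if (is.null(canonical)) return(empty_candidates())

  if (params$mode == "de-novo") {
    sorfs <- enumerate_internal_sorfs(seq, canonical, NULL,
                                      max_codons = params$max_codons,
                                      start_codons = params$start_codons_denovo)
    nt_calls <- enumerate_inframe_tis(seq, canonical, denovo_calls(seq))
  } else {
    if (is.null(tis_calls)) abort("tis-calls mode requires a TIS table")
    internal <- tis_calls[!tis_calls$is_canonical, , drop = FALSE]
    sorfs <- enumerate_internal_sorfs(seq, canonical, internal,
                                      max_codons = params$max_codons)
    nt_calls <- enumerate_inframe_tis(seq, canonical, internal)
  }
  if (!nrow(sorfs)) return(empty_candidates())
  cands <- do.call(rbind, lapply(seq_len(nrow(sorfs)), function(i) {
    pair_and_classify(sorfs[i, ], nt_calls, params, ctis = canonical$ctis)
  }))
  if (is.null(cands) || !nrow(cands)) return(empty_candidates())
  # Tie-break: highest init_score, then smaller |spacer|, then 5'-most
  # iuTIS. NA scores (de-novo) rank below any real score.
  score_key <- ifelse(is.na(cands$init_score), -Inf, cands$init_score)
  ord <- order(-score_key, abs(cands$spacer_nt), cands$iuTIS)
  best <- cands[ord[1L], , drop = FALSE]
  best$iu_kozak <- kozak_context(seq, best$iuTIS)$tier
  best$nt_kozak <- kozak_context(seq, best$ntTIS)$tier
  rownames(best) <- NULL
  best
}

#' Screen a transcriptome for iuORF candidates
#'
#' Applies [screen_transcript()] to every transcript. Transcripts whose
#' canonical TIS is absent from the TIS table are excluded (first filter
#' of the screen) and counted. TIS calls referencing unknown transcripts
#' are skipped with a warning.
#'
#' @param transcripts `data.frame` from [read_fasta()] (columns `id`,
#'   `seq`).
#' @param tis_table `data.frame` from [read_tis_table()].
#' @param params [screen_params()].
#' @return Object of class `screen_report`: counts plus the candidate
#'   table, deterministically ordered by transcript id then iuTIS.
#' @export
screen_transcriptome <- function(transcripts, tis_table,
                                 params = screen_params()) {
  stopifnot(is.data.frame(transcripts), all(c("id", "seq") %in% names(transcripts)))
  unknown <- setdiff(unique(tis_table$transcript_id), transcripts$id)
  if (length(unknown)) {
    warning(sprintf("%d TIS call(s) reference unknown transcripts; skipped",
                    sum(tis_table$transcript_id %in% unknown)))
    tis_table <- tis_table[!tis_table$transcript_id %in% unknown, , drop = FALSE]
  }
  calls_by_tx <- split(tis_table, tis_table$transcript_id)
  n_canon <- 0L
  cands <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$id[i]
    calls <- calls_by_tx[[id]]
    has_canon <- !is.null(calls) && any(calls$is_canonical)
    if (has_canon) n_canon <- n_canon + 1L
    if (!has_canon) next
    cands[[i]] <- screen_transcript(transcripts$seq[i], calls, params,
                                    transcript_id = id)
  }
  candidates <- do.call(rbind, cands)
  if (is.null(candidates)) candidates <- empty_candidates()
  candidates <- sort_candidates(candidates)
  rownames(candidates) <- NULL
  structure(list(
    n_transcripts_in = nrow(transcripts),
    n_with_canonical_tis = n_canon,
    n_candidates = nrow(candidates),
    n_upstream = sum(candidates$class == "upstream"),
    n_overlapping = sum(candidates$class == "overlapping"),
    n_skipped_tis_calls = if (length(unknown)) sum(tis_table$transcript_id %in% unknown) else 0L,
    candidates = candidates,
    params = params), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("iuORF screen report\n")
  cat(sprintf("  transcripts in:            %d\n", x$n_transcripts_in))
  cat(sprintf("  with canonical TIS call:   %d\n", x$n_with_canonical_tis))
  cat(sprintf("  candidates:                %d (%d upstream, %d overlapping)\n",
              x$n_candidates, x$n_upstream, x$n_overlapping))
  if (x$n_candidates > 0L) {
    print(utils::head(x$candidates, 10L))
    if (x$n_candidates > 10L) cat(sprintf("  ... and %d more\n", x$n_candidates - 10L))
  }
  invisible(x)
}

#' Independent re-check of a candidate against all screen filters
#'
#' Used as a property-style validator: every emitted candidate must
#' re-pass the frame, length, ordering, and spacer/overlap predicates
#' when checked directly against the sequence.
#'
#' @param cand One-row candidate `data.frame`.
#' @param seq RNA sequence string.
#' @param params [screen_params()].
#' @return `TRUE` or a character vector of violated predicates.
#' @export
validate_candidate <- function(cand, seq, params = screen_params()) {
  fails <- character(0)
  chk <- function(ok, what) if (!isTRUE(ok)) fails <<- c(fails, what)
  chk(cand$iuTIS < cand$ntTIS, "iuTIS < ntTIS")
  chk(frame_offset(cand$iuTIS, cand$cTIS) != 0L, "iuTIS out of frame")
  chk(frame_offset(cand$ntTIS, cand$cTIS) == 0L, "ntTIS in frame")
  chk(cand$iuTIS > cand$cTIS, "iuTIS internal")
  chk((cand$iuSTOP_end - cand$iuTIS + 1L) %% 3L == 0L, "iuORF multiple of 3")
  chk(substring(seq, cand$iuSTOP_end - 2L, cand$iuSTOP_end) %in% STOP_CODONS,
      "iuSTOP is a stop codon")
  chk(cand$iuORF_len_codons == (cand$iuSTOP_end - cand$iuTIS + 1L) %/% 3L - 1L,
      "length from coordinates")
  chk(cand$iuORF_len_codons <= params$max_codons, "length cap")
  chk(cand$spacer_nt == cand$ntTIS - cand$iuSTOP_end, "spacer arithmetic")
  if (identical(cand$class, "upstream")) {
    chk(cand$spacer_nt >= 1L && cand$spacer_nt <= params$max_upstream_spacer_nt,
        "upstream spacer bound")
  } else if (identical(cand$class, "overlapping")) {
    chk(cand$iuSTOP_end > cand$ntTIS, "overlap geometry")
  } else {
    fails <- c(fails, "unknown class")
  }
  # no earlier in-frame stop inside the iuORF
  if (cand$iuSTOP_end - 2L > cand$iuTIS) {
    body_starts <- seq.int(cand$iuTIS, cand$iuSTOP_end - 3L, by = 3L)
    chk(!any(substring(seq, body_starts, body_starts + 2L) %in% STOP_CODONS),
        "first in-frame stop")
  }
  if (length(fails)) fails else TRUE
}
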