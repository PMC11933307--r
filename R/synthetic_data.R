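# Certified synthetic inputs.
#
# Each generator is a pure function of (specification, seed) and emits
# data with the statistical/geometric structure the pipeline assumes,
# together with ground truth. Transcripts are built by planting the
# requested geometry and then scrubbing accidental signal (stray AUGs,
# premature stops) by rejection-resampling of unprotected residues, so
# that a brute-force certificate ("the only start codons are the planted
# ones") holds at generation time. Unrealizable requests fail loudly.

KOZAK_TEMPLATES <- list(
  optimal  = list(pre = "GCCACC", p4 = "G"),
  strong   = list(pre = "CAAACC", p4 = "G"),
  adequate = list(pre = "ACCCCC", p4 = "G"),  # C at -3, G at +4: "CCC AUG G"-like
  weak     = list(pre = "CUUUUU", p4 = "U")
)

#' Specification of a planted transcript
#'
#' Defaults state the emulated world: a ~600-nt mRNA with a 50-nt 5'
#' leader, an iuORF of 35 coding codons in a "CCC AUG G"-like context
#' with a 14-nt spacer to the truncated-proteoform TIS (the wild-type
#' geometry of the motivating example), a canonical TIS in an adequate
#' context, and initiation scores dominated by the canonical TIS.
#'
#' Mod-3 realizability: with the ntTIS in frame 0, an upstream spacer
#' satisfies `spacer mod 3 != 1` and an overlap satisfies
#' `overlap mod 3 != 2`; other values are geometrically impossible and
#' rejected.
#'
#' @param klass `"upstream"`, `"overlapping"` or `"none"`.
#' @param iuORF_len_codons iuORF length in coding codons.
#' @param spacer_nt Upstream spacer (stop end to ntTIS).
#' @param overlap_nt Overlap (stop end minus ntTIS) for the overlapping
#'   class.
#' @param c_kozak_tier,iu_kozak_tier,nt_kozak_tier Requested context
#'   tiers (see [classify_kozak()]).
#' @param init_scores Named numeric: initiation scores for `cTIS`,
#'   `iuTIS`, `ntTIS`.
#' @param transcript_len,utr5_len,utr3_len Layout in nucleotides.
#' @param dist_cTIS_to_iuTIS Optional distance from cTIS to iuTIS; the
#'   default is the smallest value >= 45 in the required frame.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(klass = c("upstream", "overlapping", "none"),
                       iuORF_len_codons = 35L, spacer_nt = 14L,
                       overlap_nt = 6L,
                       c_kozak_tier = "adequate",
                       iu_kozak_tier = "adequate",
                       nt_kozak_tier = "weak",
                       init_scores = c(cTIS = 50, iuTIS = 5, ntTIS = 2),
                       transcript_len = 600L, utr5_len = 50L,
                       utr3_len = 50L, dist_cTIS_to_iuTIS = NULL) {
  klass <- match.arg(klass)
  tiers <- c(c_kozak_tier, iu_kozak_tier, nt_kozak_tier)
  if (!all(tiers %in% names(KOZAK_TEMPLATES))) {
    abort("tiers must be one of: %s", paste(names(KOZAK_TEMPLATES), collapse = ", "))
  }
  if (!is_count(iuORF_len_codons, 1L)) abort("iuORF_len_codons must be >= 1")
  structure(list(klass = klass,
                 iuORF_len_codons = as.integer(iuORF_len_codons),
                 spacer_nt = as.integer(spacer_nt),
                 overlap_nt = as.integer(overlap_nt),
                 c_kozak_tier = c_kozak_tier, iu_kozak_tier = iu_kozak_tier,
                 nt_kozak_tier = nt_kozak_tier, init_scores = init_scores,
                 transcript_len = as.integer(transcript_len),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 dist_cTIS_to_iuTIS = if (is.null(dist_cTIS_to_iuTIS)) NULL
                                      else as.integer(dist_cTIS_to_iuTIS)),
            class = "plant_spec")
}

# Resolve the planted coordinates for a spec; errors on unrealizable
# geometry. Returns a list of anchor positions.
plant_layout <- function(spec) {
  ctis <- spec$utr5_len + 1L
  len <- spec$transcript_len
  cds_nt <- ((len - spec$utr3_len - ctis + 1L) %/% 3L) * 3L
  if (cds_nt < 30L) abort("transcript too short for a canonical ORF")
  cstop_end <- ctis + cds_nt - 1L
  out <- list(ctis = ctis, cstop_end = cstop_end,
              iutis = NA_integer_, iustop_end = NA_integer_,
              nttis = NA_integer_)
  if (spec$klass == "none") {
    # give decoys an internal in-frame TIS but no sORF
    nttis <- ctis + 120L
    if (nttis >= cstop_end - 2L) nttis <- ctis + 30L
    if (nttis >= cstop_end - 2L) abort("transcript too short to place an ntTIS")
    out$nttis <- nttis
    return(out)
  }
  if (spec$klass == "upstream") {
    if (spec$spacer_nt < 1L) abort("upstream spacer must be >= 1")
    f_req <- (1L - spec$spacer_nt) %% 3L
    if (f_req == 0L) {
      abort("spacer %d nt is geometrically impossible (spacer mod 3 == 1 %s)",
            spec$spacer_nt, "would put the ntTIS out of frame")
    }
  } else {
    if (spec$overlap_nt < 1L) abort("overlap must be >= 1")
    f_req <- (spec$overlap_nt - 2L) %% 3L
    if (f_req == 0L) {
      abort("overlap %d nt is geometrically impossible (overlap mod 3 == 2 %s)",
            spec$overlap_nt, "would put the ntTIS out of frame")
    }
  }
  dist <- spec$dist_cTIS_to_iuTIS %||% (45L + ((f_req - 45L) %% 3L))
  if (dist %% 3L != f_req) {
    abort("dist_cTIS_to_iuTIS %d is in frame %d but the requested %s geometry requires frame %d",
          dist, dist %% 3L, spec$klass, f_req)
  }
  if (dist < 9L) abort("dist_cTIS_to_iuTIS must be >= 9")
  iutis <- ctis + dist
  iustop_end <- iutis + 3L * (spec$iuORF_len_codons + 1L) - 1L
  nttis <- if (spec$klass == "upstream") iustop_end + spec$spacer_nt
           else iustop_end - spec$overlap_nt
  if (spec$klass == "overlapping" && nttis <= iutis) {
    abort("overlap %d nt exceeds the iuORF span", spec$overlap_nt)
  }
  if (max(iustop_end, nttis + 2L) >= cstop_end - 2L) {
    abort("planted geometry does not fit inside the canonical ORF (needs %d nt, cSTOP at %d)",
          max(iustop_end, nttis + 2L), cstop_end)
  }
  out$iutis <- iutis
  out$iustop_end <- iustop_end
  out$nttis <- nttis
  out
}

# Write `chars` at `pos`; mandatory writes must not conflict with an
# existing protected residue, cosmetic writes are skipped on conflict.
plant_write <- function(state, pos, chars, mandatory = TRUE) {
  chars <- strsplit(chars, "", fixed = TRUE)[[1L]]
  idx <- seq.int(pos, pos + length(chars) - 1L)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i < 1L || i > length(state$seq)) {
      if (mandatory) abort("planted element runs outside the transcript")
      next
    }
    if (state$protected[i]) {
      if (state$seq[i] != chars[k]) {
        if (mandatory) {
          abort("conflicting planted elements at position %d ('%s' vs '%s'): %s",
                i, state$seq[i], chars[k],
                "the requested tiers/geometry are unrealizable")
        }
        next
      }
    }
    state$seq[i] <- chars[k]
    state$protected[i] <- TRUE
  }
  state
}

plant_context <- function(state, pos, tier) {
  tmpl <- KOZAK_TEMPLATES[[tier]]
  # -3 and +4 determine the tier (plus the full -6..-1 run for optimal)
  state <- plant_write(state, pos - 3L, substr(tmpl$pre, 4L, 4L))
  state <- plant_write(state, pos + 3L, tmpl$p4)
  mandatory_pre <- identical(tier, "optimal")
  state <- plant_write(state, pos - 6L, substr(tmpl$pre, 1L, 3L), mandatory_pre)
  state <- plant_write(state, pos - 2L, substr(tmpl$pre, 5L, 6L), mandatory_pre)
  state
}

#' Generate one transcript with a planted iuORF geometry
#'
#' Constructs a canonical ORF with the requested cTIS context, plants an
#' out-of-frame short ORF and an in-frame internal TIS at the requested
#' geometry (or neither, for `klass = "none"`, which still carries an
#' internal in-frame TIS as a decoy), scrubs accidental AUGs and
#' premature stops by rejection-resampling, and emits TIS calls with the
#' requested initiation scores. Deterministic per seed.
#'
#' @param spec A [plant_spec()].
#' @param seed Integer seed.
#' @param transcript_id Identifier.
#' @return List with `record` (one-row `data.frame`: `id`,
#'   `description`, `seq`), `tis_calls`, and `truth` (planted candidate
#'   or `NULL`, anchors, and `certificate = TRUE` once brute-force
#'   checked).
#' @export
generate_transcript <- function(spec, seed = 1L, transcript_id = "synth_0001") {
  stopifnot(inherits(spec, "plant_spec"))
  lay <- plant_layout(spec)
  with_seed(seed, {
    state <- new.env()
    state$seq <- sample(RNA_BASES, spec$transcript_len, replace = TRUE)
    state$protected <- logical(spec$transcript_len)

    # plant all codons first, then contexts: cosmetic context residues
    # must never pre-empt a mandatory codon position
    state <- plant_write(state, lay$ctis, "AUG")
    state <- plant_write(state, lay$cstop_end - 2L, "UAA")
    if (!is.na(lay$nttis)) state <- plant_write(state, lay$nttis, "AUG")
    if (!is.na(lay$iutis)) {
      state <- plant_write(state, lay$iutis, "AUG")
      state <- plant_write(state, lay$iustop_end - 2L, "UAA")
    }
    state <- plant_context(state, lay$ctis, spec$c_kozak_tier)
    if (!is.na(lay$nttis)) state <- plant_context(state, lay$nttis, spec$nt_kozak_tier)
    if (!is.na(lay$iutis)) state <- plant_context(state, lay$iutis, spec$iu_kozak_tier)
    planted_starts <- sort(stats::na.omit(c(lay$ctis, lay$iutis, lay$nttis)))
    tis_tiers <- list(list(pos = lay$ctis, tier = spec$c_kozak_tier))
    if (!is.na(lay$iutis)) {
      tis_tiers <- c(tis_tiers, list(list(pos = lay$iutis,
                                          tier = spec$iu_kozak_tier)))
    }
    if (!is.na(lay$nttis)) {
      tis_tiers <- c(tis_tiers, list(list(pos = lay$nttis,
                                          tier = spec$nt_kozak_tier)))
    }
    scrub_transcript(state, lay, spec, planted_starts, tis_tiers)
    seq <- paste(state$seq, collapse = "")

    calls <- data.frame(
      transcript_id = transcript_id,
      pos = c(lay$ctis,
              if (!is.na(lay$iutis)) lay$iutis,
              if (!is.na(lay$nttis)) lay$nttis),
      codon = "AUG",
      init_score = unname(c(spec$init_scores[["cTIS"]],
                            if (!is.na(lay$iutis)) spec$init_scores[["iuTIS"]],
                            if (!is.na(lay$nttis)) spec$init_scores[["ntTIS"]])),
      is_canonical = c(TRUE,
                       if (!is.na(lay$iutis)) FALSE,
                       if (!is.na(lay$nttis)) FALSE),
      stringsAsFactors = FALSE)

    truth_cand <- NULL
    if (spec$klass != "none") {
      truth_cand <- data.frame(
        transcript_id = transcript_id, cTIS = lay$ctis, iuTIS = lay$iutis,
        iuSTOP_end = lay$iustop_end, ntTIS = lay$nttis,
        class = spec$klass,
        spacer_nt = spacer_nt(lay$iustop_end, lay$nttis),
        iuORF_len_codons = spec$iuORF_len_codons,
        iu_kozak = spec$iu_kozak_tier, nt_kozak = spec$nt_kozak_tier,
        init_score = unname(spec$init_scores[["iuTIS"]]),
        stringsAsFactors = FALSE)
    }
    # brute-force certificate: the only start codons in the transcript
    # are the planted ones, so no unplanted candidate can exist in
    # either screen mode.
    certificate <- identical(find_triplet(seq, "AUG"),
                             as.integer(planted_starts))
    if (!certificate) abort("internal error: decoy scrub failed certification")
    if (!is.null(truth_cand)) {
      v <- validate_candidate(truth_cand, seq,
                              screen_params(max_codons =
                                              max(100L, spec$iuORF_len_codons)))
      if (!isTRUE(v)) abort("internal error: planted candidate invalid (%s)",
                            paste(v, collapse = "; "))
    }
    list(record = data.frame(id = transcript_id,
                             description = sprintf("synthetic %s iuORF transcript",
                                                   spec$klass),
                             seq = seq, stringsAsFactors = FALSE),
         tis_calls = calls,
         truth = list(candidate = truth_cand, ctis = lay$ctis,
                      cstop_end = lay$cstop_end, certificate = certificate))
  })
}

# Rejection-resampling scrub. Violations: (1) AUG anywhere except the
# planted starts; (2) premature stop in the canonical frame inside the
# CDS; (3) premature stop in the iuORF frame inside the iuORF. Each
# offending triplet has its unprotected residues resampled; a fully
# protected violation cannot occur by construction of the templates and
# is reported as unrealizable.
scrub_transcript <- function(state, lay, spec, planted_starts, tis_tiers,
                             max_pass = 500L) {
  for (pass in seq_len(max_pass)) {
    seq <- paste(state$seq, collapse = "")
    bad3 <- setdiff(find_triplet(seq, "AUG"), planted_starts)
    canon_frame <- seq.int(lay$ctis, lay$cstop_end - 5L, by = 3L)
    bad3 <- c(bad3, canon_frame[substring(seq, canon_frame, canon_frame + 2L) %in%
                                  STOP_CODONS])
    if (!is.na(lay$iutis) && lay$iustop_end - 5L >= lay$iutis) {
      iu_frame <- seq.int(lay$iutis, lay$iustop_end - 5L, by = 3L)
      bad3 <- c(bad3, iu_frame[substring(seq, iu_frame, iu_frame + 2L) %in%
                                 STOP_CODONS])
    }
    # a random -6..-1 run can accidentally upgrade a requested tier
    # (strong -> optimal); resample the window's free residues
    bad_win <- integer(0)
    for (tt in tis_tiers) {
      if (kozak_context(seq, tt$pos)$tier != tt$tier) {
        bad_win <- c(bad_win, max(1L, tt$pos - 6L))
      }
    }
    bad <- list()
    if (length(bad3)) bad <- c(bad, lapply(unique(bad3), function(p) p:(p + 2L)))
    if (length(bad_win)) bad <- c(bad, lapply(bad_win, function(p) p:(p + 9L)))
    if (!length(bad)) return(invisible(state))
    for (idx in bad) {
      idx <- idx[idx >= 1L & idx <= length(state$seq)]
      free <- idx[!state$protected[idx]]
      if (!length(free)) {
        abort("cannot scrub violation at position %d: all residues are planted",
              idx[1L])
      }
      state$seq[free] <- sample(RNA_BASES, length(free), replace = TRUE)
    }
  }
  abort("decoy scrub did not converge after %d passes", max_pass)
}

#' Synthetic transcript mirroring the published worked-example geometry
#'
#' A stand-in (not the real mRNA) reproducing the printed coordinates of
#' the mouse *Trip6* worked example: canonical TIS at 141, out-of-frame
#' iuORF spanning 359-466 (35 coding codons, "CCC AUG G"-like context),
#' a 14-nt spacer, and the truncated-proteoform AUG at 480, in-frame
#' with the canonical start.
#'
#' @param seed Integer seed.
#' @return As [generate_transcript()].
#' @export
trip6_like_transcript <- function(seed = 106L) {
  spec <- plant_spec(klass = "upstream", iuORF_len_codons = 35L,
                     spacer_nt = 14L, c_kozak_tier = "adequate",
                     iu_kozak_tier = "adequate", nt_kozak_tier = "weak",
                     transcript_len = 800L, utr5_len = 140L, utr3_len = 60L,
                     dist_cTIS_to_iuTIS = 218L)
  generate_transcript(spec, seed, transcript_id = "Trip6_like_synthetic")
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Draws transcript classes from `class_mix`, generates each transcript
#' with a per-transcript sub-seed, and optionally writes the FASTA and
#' TIS-table inputs consumed by the screen plus a truth table.
#'
#' @param n Number of transcripts.
#' @param class_mix Named probabilities over
#'   `upstream`/`overlapping`/`none`; must sum to 1.
#' @param seed Integer seed.
#' @param fasta_path,tis_path,truth_path Optional output paths.
#' @param vary Randomize iuORF length (5-60 codons) and spacer/overlap
#'   within their realizable ranges (default `TRUE`).
#' @return List with `transcripts`, `tis_table`, `truth` (one row per
#'   transcript; `NA` coordinates for class `"none"`).
#' @export
generate_transcriptome <- function(n,
                                   class_mix = c(upstream = 0.12,
                                                 overlapping = 0.08,
                                                 none = 0.80),
                                   seed = 1L,
                                   fasta_path = NULL, tis_path = NULL,
                                   truth_path = NULL, vary = TRUE) {
  if (!is_count(n, 0L)) abort("n must be a non-negative integer")
  if (abs(sum(class_mix) - 1) > 1e-8) abort("class_mix must sum to 1")
  if (!all(names(class_mix) %in% c("upstream", "overlapping", "none"))) {
    abort("class_mix names must be upstream/overlapping/none")
  }
  # realizable ranges: spacer mod 3 != 1 and >= 5 (the planted context
  # window must clear the iuORF stop codon); overlap mod 3 != 2 and >= 6
  upstream_spacers <- setdiff(5:30, seq(1L, 30L, by = 3L))
  overlap_choices <- setdiff(6:24, seq(2L, 24L, by = 3L))
  res <- with_seed(seed, {
    if (n == 0L) {
      classes <- character(0); sub_seeds <- integer(0)
      lens <- integer(0); geom <- integer(0)
    } else {
      classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
      sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
      lens <- if (vary) sample(5:60, n, replace = TRUE) else rep(35L, n)
      geom <- vapply(seq_len(n), function(i) {
        if (classes[i] == "upstream") {
          sample(upstream_spacers, 1L)
        } else if (classes[i] == "overlapping") {
          # overlap must leave room for the ntTIS context inside the iuORF
          ok <- overlap_choices[overlap_choices <= 3L * lens[i] - 7L]
          sample(ok, 1L)
        } else NA_integer_
      }, integer(1))
    }
    list(classes = classes, sub_seeds = sub_seeds, lens = lens, geom = geom)
  })
  txs <- vector("list", n); calls <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("synth_%04d", i)
    spec <- plant_spec(klass = res$classes[i],
                       iuORF_len_codons = res$lens[i],
                       spacer_nt = if (res$classes[i] == "upstream") res$geom[i] else 14L,
                       overlap_nt = if (res$classes[i] == "overlapping") res$geom[i] else 6L)
    g <- generate_transcript(spec, seed = res$sub_seeds[i], transcript_id = id)
    txs[[i]] <- g$record
    calls[[i]] <- g$tis_calls
    truths[[i]] <- if (is.null(g$truth$candidate)) {
      data.frame(transcript_id = id, class = "none", cTIS = g$truth$ctis,
                 iuTIS = NA_integer_, iuSTOP_end = NA_integer_,
                 ntTIS = NA_integer_, spacer_nt = NA_integer_,
                 iuORF_len_codons = NA_integer_, stringsAsFactors = FALSE)
    } else {
      cbind(g$truth$candidate[, c("transcript_id", "class", "cTIS", "iuTIS",
                                  "iuSTOP_end", "ntTIS", "spacer_nt",
                                  "iuORF_len_codons")])
    }
  }
  transcripts <- if (n) do.call(rbind, txs) else
    data.frame(id = character(0), description = character(0),
               seq = character(0), stringsAsFactors = FALSE)
  tis_table <- if (n) do.call(rbind, calls) else
    data.frame(transcript_id = character(0), pos = integer(0),
               codon = character(0), init_score = numeric(0),
               is_canonical = logical(0), stringsAsFactors = FALSE)
  truth <- if (n) do.call(rbind, truths) else
    data.frame(transcript_id = character(0), class = character(0),
               cTIS = integer(0), iuTIS = integer(0), iuSTOP_end = integer(0),
               ntTIS = integer(0), spacer_nt = integer(0),
               iuORF_len_codons = integer(0), stringsAsFactors = FALSE)
  if (!is.null(fasta_path)) write_fasta(transcripts, fasta_path)
  if (!is.null(tis_path)) {
    utils::write.table(tis_table, tis_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(transcripts = transcripts, tis_table = tis_table, truth = truth)
}

#' Generate an ortholog trio with conserved geometry and divergent sORF
#' codons
#'
#' Starting from a reference transcript, two "species" copies are made
#' by substituting residues at the given rate everywhere except the
#' feature anchors (start codons, stop codons, and the -6..-1/+4 context
#' residues of each planted TIS). Substitutions that would introduce a
#' premature in-frame stop into the iuORF are reverted, preserving its
#' length and stop placement while randomizing its codons.
#'
#' @param spec A [plant_spec()] for the reference.
#' @param divergence Per-site substitution probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param species Tags for the non-reference sequences.
#' @return List with `reference` (record), `others` (`data.frame` of
#'   mutated records), `anchors`, and `truth` (the reference candidate).
#' @export
generate_ortholog_trio <- function(spec = plant_spec(), divergence = 0.1,
                                   seed = 1L,
                                   species = c("human", "rat")) {
  if (divergence < 0 || divergence >= 0.5) abort("divergence must be in [0, 0.5)")
  ref <- generate_transcript(spec, seed, transcript_id = "mouse")
  lay <- plant_layout(spec)
  n <- spec$transcript_len
  anchor_idx <- function(pos) {
    if (is.na(pos)) return(integer(0))
    c(pos:(pos + 2L), (pos - 6L):(pos - 1L), pos + 3L)
  }
  protected <- unique(c(
    anchor_idx(lay$ctis), anchor_idx(lay$iutis), anchor_idx(lay$nttis),
    if (!is.na(lay$iustop_end)) (lay$iustop_end - 2L):lay$iustop_end,
    (lay$cstop_end - 2L):lay$cstop_end))
  protected <- protected[protected >= 1L & protected <= n]
  others <- with_seed(seed + 1L, {
    lapply(seq_along(species), function(s) {
      chars <- strsplit(ref$record$seq, "", fixed = TRUE)[[1L]]
      eligible <- setdiff(seq_len(n), protected)
      mutate <- eligible[stats::runif(length(eligible)) < divergence]
      for (i in mutate) chars[i] <- sample(setdiff(RNA_BASES, chars[i]), 1L)
      # revert substitutions that created a premature stop in the iuORF
      if (!is.na(lay$iutis) && lay$iustop_end - 5L >= lay$iutis) {
        repeat {
          seq_s <- paste(chars, collapse = "")
          iu_frame <- seq.int(lay$iutis, lay$iustop_end - 5L, by = 3L)
          bad <- iu_frame[substring(seq_s, iu_frame, iu_frame + 2L) %in%
                            STOP_CODONS]
          if (!length(bad)) break
          ref_chars <- strsplit(ref$record$seq, "", fixed = TRUE)[[1L]]
          for (p in bad) chars[p:(p + 2L)] <- ref_chars[p:(p + 2L)]
        }
      }
      data.frame(id = species[s], description = "synthetic ortholog",
                 seq = paste(chars, collapse = ""), stringsAsFactors = FALSE)
    })
  })
  list(reference = ref$record, others = do.call(rbind, others),
       anchors = lay, truth = ref$truth)
}

#' Generate a kinase-screen ratio table with spiked hits
#'
#' Baseline ratios are drawn from a truncated-positive normal; hits are
#' shifted upward by `effect_sd_units` standard deviations. Defaults
#' emulate a 184-kinase plate with 16 empty-vector control wells and a
#' baseline ratio of 0.04 +/- 0.015.
#'
#' @param n Number of kinase entries.
#' @param n_hits Number of spiked entries.
#' @param effect_sd_units Shift of the hits, in units of the baseline
#'   standard deviation.
#' @param seed Integer seed.
#' @param mu,sigma Baseline mean and SD of the ratio.
#' @param n_controls Number of empty-vector control wells.
#' @return List with `table` (`label`, `ratio`), `hit_labels`,
#'   `control_labels`.
#' @export
generate_screen_ratios <- function(n = 184L, n_hits = 8L,
                                   effect_sd_units = 2.5, seed = 1L,
                                   mu = 0.04, sigma = 0.015,
                                   n_controls = 16L) {
  if (n_hits > n) abort("n_hits must be <= n")
  with_seed(seed, {
    rpos <- function(k) {
      x <- stats::rnorm(k, mu, sigma)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sigma)
      x
    }
    ratios <- rpos(n)
    hits <- sort(sample.int(n, n_hits))
    ratios[hits] <- ratios[hits] + effect_sd_units * sigma
    labels <- sprintf("kinase_%03d", seq_len(n))
    control_labels <- if (n_controls > 0L) sprintf("vector_%02d", seq_len(n_controls))
                      else character(0)
    tab <- data.frame(label = c(labels, control_labels),
                      ratio = c(ratios, if (n_controls > 0L) rpos(n_controls)),
                      stringsAsFactors = FALSE)
    list(table = tab, hit_labels = labels[hits],
         control_labels = control_labels)
  })
}

#' Generate replicate Ct records for a known initiation index
#'
#' Ct values are constructed so that the noiseless delta-delta-Ct equals
#' `-log2(true_index)`, then Gaussian cycle noise is added to each of
#' the four wells independently.
#'
#' @param true_index True initiation index (> 0).
#' @param noise_sd_cycles SD of the per-well Ct noise, in cycles.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return List with `records` ([read_ct_table()] layout) and
#'   `true_index`.
#' @export
generate_ct_table <- function(true_index, noise_sd_cycles = 0.2,
                              n_reps = 3L, seed = 1L) {
  if (!is.numeric(true_index) || true_index <= 0) {
    abort("true_index must be positive")
  }
  with_seed(seed, {
    base <- data.frame(
      replicate = seq_len(n_reps),
      ct_target_tis = 25 - log2(true_index),
      ct_target_bg = 30,
      ct_ref_tis = 24,
      ct_ref_bg = 29)
    for (col in c("ct_target_tis", "ct_target_bg", "ct_ref_tis", "ct_ref_bg")) {
      base[[col]] <- base[[col]] + stats::rnorm(n_reps, 0, noise_sd_cycles)
    }
    list(records = base, true_index = true_index)
  })
}
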