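# Cross-species conservation of iuORF features.
#
# The features that matter for repression of a downstream TIS are the
# start-codon contexts, the short-ORF length, and the distances (spacer,
# cTIS-to-iuTIS). They are compared across species after projecting the
# reference anchors through a global pairwise alignment. Closest-ortholog
# selection uses alignment identity, which for the two-to-three-species
# setting is equivalent to (and much simpler than) building a guide tree.

# Global (Needleman-Wunsch) alignment with fixed scoring: match +1,
# mismatch -1, linear gap -2. Deterministic tie-break: diagonal, then
# up (gap in b), then left (gap in a).
needleman_wunsch <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  GAP <- -2
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- GAP * (0:n)
  F[1L, ] <- GAP * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], 1, -1)
    prev <- F[i, ]
    cur <- numeric(m + 1L)
    cur[1L] <- GAP * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + GAP, cur[j] + GAP)
    }
    F[i + 1L, ] <- cur
  }
  # traceback
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] == F[i, j] + (if (av[i] == bv[j]) 1 else -1)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + GAP) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = F[n + 1L, m + 1L])
}

#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch with match +1, mismatch -1, linear gap -2 (fixed,
#' documented scoring). Works for nucleotide or amino-acid strings.
#'
#' @param a,b Sequence strings.
#' @param id_a,id_b Identifiers stored with the alignment.
#' @return Object of class `pairwise_alignment`: list with `ids`,
#'   `aligned` (two gapped strings), `score`, `identity` (matching
#'   columns / alignment columns).
#' @export
align_pair <- function(a, b, id_a = "a", id_b = "b") {
  if (!is_string(a) || !is_string(b) || !nzchar(a) || !nzchar(b)) {
    abort("both sequences must be non-empty strings")
  }
  nw <- needleman_wunsch(a, b)
  ca <- strsplit(nw$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(nw$b, "", fixed = TRUE)[[1L]]
  structure(list(ids = c(id_a, id_b),
                 aligned = stats::setNames(c(nw$a, nw$b), c(id_a, id_b)),
                 score = nw$score,
                 identity = sum(ca == cb & ca != "-") / length(ca)),
            class = "pairwise_alignment")
}

#' Fraction of identical columns in a global alignment
#'
#' @param a,b Sequence strings (nucleotide or amino-acid).
#' @return Identity in `[0, 1]`: matches / alignment columns.
#' @export
pairwise_identity <- function(a, b) {
  align_pair(a, b)$identity
}

#' Select the closest ortholog by alignment identity
#'
#' @param reference One-row `data.frame` (columns `id`, `seq`) or a
#'   sequence string.
#' @param candidates `data.frame` of candidate orthologs (columns `id`,
#'   `seq`), at least one row.
#' @return The selected candidate row; ties are resolved by id order
#'   (reported via a message).
#' @export
select_closest_ortholog <- function(reference, candidates) {
  ref_seq <- if (is.data.frame(reference)) reference$seq[1L] else reference
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort("at least one candidate ortholog is required")
  }
  ident <- vapply(candidates$seq, pairwise_identity, numeric(1), a = ref_seq)
  best <- which(ident == max(ident))
  if (length(best) > 1L) {
    best <- best[order(candidates$id[best])]
    message(sprintf("identity tie (%.3f); selecting '%s' by id order",
                    max(ident), candidates$id[best[1L]]))
  }
  out <- candidates[best[1L], , drop = FALSE]
  out$identity <- max(ident)
  rownames(out) <- NULL
  out
}

#' Project a position through a pairwise alignment
#'
#' @param alignment A `pairwise_alignment` from [align_pair()].
#' @param from_id Id of the sequence `pos` refers to.
#' @param pos 1-based (ungapped) position in the `from` sequence.
#' @param to_id Id of the target sequence.
#' @return 1-based position in the target sequence, or `NA_integer_`
#'   when the aligned column is a gap in the target.
#' @export
project_position <- function(alignment, from_id, pos, to_id) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (!from_id %in% alignment$ids || !to_id %in% alignment$ids) {
    abort("id not in alignment: %s",
          setdiff(c(from_id, to_id), alignment$ids)[1L])
  }
  from <- strsplit(alignment$aligned[[from_id]], "", fixed = TRUE)[[1L]]
  to <- strsplit(alignment$aligned[[to_id]], "", fixed = TRUE)[[1L]]
  from_pos <- cumsum(from != "-")
  col <- match(pos, from_pos)
  if (is.na(col) || from[col] == "-") {
    abort("position %d outside the ungapped '%s' sequence", pos, from_id)
  }
  if (to[col] == "-") return(NA_integer_)
  as.integer(sum(to[seq_len(col)] != "-"))
}

#' Translate an RNA ORF to its peptide (stop excluded)
#'
#' Standard genetic code ([Biostrings::GENETIC_CODE]); translation stops
#' at the first in-frame stop codon; codons containing N give `X`.
#'
#' @param seq RNA sequence string.
#' @param start 1-based start position.
#' @param stop_end Optional last nucleotide of the stop codon; when
#'   given, exactly the codons in `[start, stop_end - 3]` are
#'   translated.
#' @return Amino-acid string.
#' @export
translate_orf <- function(seq, start, stop_end = NULL) {
  n <- if (is.null(stop_end)) nchar(seq) else stop_end
  if (start + 2L > n) return("")
  codon_starts <- seq.int(start, n - 2L, by = 3L)
  codons <- substring(seq, codon_starts, codon_starts + 2L)
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("T", "U", names(code))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  first_stop <- which(aa == "*")
  if (length(first_stop)) aa <- aa[seq_len(first_stop[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Extract the per-species feature vector for an iuORF candidate
#'
#' Reads codons at the (projected) anchor positions, re-extends the
#' short ORF in this species to its own stop (species-specific length
#' and spacer), and attaches Kozak tiers. Anchors projected to a gap
#' yield `"absent"` features rather than an error.
#'
#' @param seq RNA sequence string for this species.
#' @param ctis,iutis,nttis Projected anchor positions (`NA` = gap).
#' @param species Species tag recorded in the row.
#' @return One-row `data.frame`: `species`, `cTIS_context_tier`,
#'   `iu_start_codon`, `iu_context_tier`, `nt_start_codon`,
#'   `nt_context_tier`, `iuORF_len_codons`, `spacer_nt`,
#'   `dist_cTIS_to_iuTIS`, `sorf_peptide`.
#' @export
feature_vector <- function(seq, ctis, iutis, nttis, species = "reference") {
  n <- nchar(seq)
  tier_at <- function(pos) {
    if (is.na(pos) || pos + 2L > n) "absent" else kozak_context(seq, pos)$tier
  }
  codon_at_safe <- function(pos) {
    if (is.na(pos) || pos + 2L > n) "absent" else codon_at(seq, pos)
  }
  iu_len <- NA_integer_; sp <- NA_integer_; pep <- NA_character_
  if (!is.na(iutis) && iutis + 2L <= n) {
    orf <- extend_orf(seq, iutis)
    if (!is.null(orf)) {
      iu_len <- orf$len_codons
      pep <- translate_orf(seq, iutis, orf$stop_end)
      if (!is.na(nttis)) sp <- spacer_nt(orf$stop_end, nttis)
    }
  }
  data.frame(
    species = species,
    cTIS_context_tier = tier_at(ctis),
    iu_start_codon = codon_at_safe(iutis),
    iu_context_tier = tier_at(iutis),
    nt_start_codon = codon_at_safe(nttis),
    nt_context_tier = tier_at(nttis),
    iuORF_len_codons = iu_len,
    spacer_nt = sp,
    dist_cTIS_to_iuTIS = if (is.na(ctis) || is.na(iutis)) NA_integer_
                         else as.integer(iutis - ctis),
    sorf_peptide = pep,
    stringsAsFactors = FALSE)
}

#' Cross-species conservation report for iuORF features
#'
#' Codon and context-tier features are conserved iff they match exactly
#' in every species; the ORF length and the distances are conserved
#' within stated tolerances. The short-ORF peptide identity (minimum
#' over non-reference species, global alignment of amino acids) probes
#' whether the *coding sequence* - as opposed to the geometry - is
#' conserved.
#'
#' @param ref Reference [feature_vector()] row.
#' @param others `data.frame` of non-reference feature vectors.
#' @param len_tol_codons Tolerance for `iuORF_len_codons` (default 2).
#' @param dist_tol_nt Tolerance for `spacer_nt` and
#'   `dist_cTIS_to_iuTIS` (default 6).
#' @return Object of class `conservation_report`: named logical flags
#'   plus `sorf_peptide_identity`.
#' @export
conservation_report <- function(ref, others, len_tol_codons = 2L,
                                dist_tol_nt = 6L) {
  stopifnot(is.data.frame(ref), nrow(ref) == 1L, is.data.frame(others),
            nrow(others) >= 1L)
  exact <- function(col) {
    all(!is.na(others[[col]]) & others[[col]] != "absent" &
          others[[col]] == ref[[col]])
  }
  within_tol <- function(col, tol) {
    all(!is.na(others[[col]]) & abs(others[[col]] - ref[[col]]) <= tol)
  }
  peptide_id <- if (is.na(ref$sorf_peptide) || any(is.na(others$sorf_peptide)) ||
                    !nzchar(ref$sorf_peptide)) {
    NA_real_
  } else {
    min(vapply(others$sorf_peptide, pairwise_identity, numeric(1),
               a = ref$sorf_peptide))
  }
  structure(list(
    flags = c(
      cTIS_context = exact("cTIS_context_tier"),
      iu_start_codon = exact("iu_start_codon"),
      iu_context = exact("iu_context_tier"),
      nt_start_codon = exact("nt_start_codon"),
      nt_context = exact("nt_context_tier"),
      iuORF_len = !is.na(ref$iuORF_len_codons) &&
        within_tol("iuORF_len_codons", len_tol_codons),
      spacer = !is.na(ref$spacer_nt) && within_tol("spacer_nt", dist_tol_nt),
      dist_cTIS_to_iuTIS = !is.na(ref$dist_cTIS_to_iuTIS) &&
        within_tol("dist_cTIS_to_iuTIS", dist_tol_nt)),
    sorf_peptide_identity = peptide_id,
    n_species = nrow(others) + 1L,
    len_tol_codons = len_tol_codons,
    dist_tol_nt = dist_tol_nt), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("Conservation report (%d species)\n", x$n_species))
  for (f in names(x$flags)) {
    cat(sprintf("  %-20s %s\n", f, if (x$flags[[f]]) "conserved" else "NOT conserved"))
  }
  cat(sprintf("  sORF peptide identity: %s\n",
              ifelse(is.na(x$sorf_peptide_identity), "NA",
                     sprintf("%.3f", x$sorf_peptide_identity))))
  invisible(x)
}

#' Conservation analysis of one candidate against ortholog sequences
#'
#' Aligns each ortholog to the reference, projects the candidate's
#' anchors (cTIS, iuTIS, ntTIS), extracts per-species feature vectors,
#' and summarizes conservation.
#'
#' @param ref_seq Reference RNA sequence string.
#' @param candidate One-row candidate `data.frame` (reference
#'   coordinates).
#' @param orthologs `data.frame` (columns `id`, `seq`) of ortholog
#'   sequences.
#' @param ... Passed to [conservation_report()].
#' @return List with `features` (one row per species, reference first)
#'   and `report`.
#' @export
conserve_candidate <- function(ref_seq, candidate, orthologs, ...) {
  ref_fv <- feature_vector(ref_seq, candidate$cTIS, candidate$iuTIS,
                           candidate$ntTIS, species = "reference")
  rows <- lapply(seq_len(nrow(orthologs)), function(i) {
    aln <- align_pair(ref_seq, orthologs$seq[i], "ref", orthologs$id[i])
    proj <- function(p) project_position(aln, "ref", p, orthologs$id[i])
    feature_vector(orthologs$seq[i], proj(candidate$cTIS),
                   proj(candidate$iuTIS), proj(candidate$ntTIS),
                   species = orthologs$id[i])
  })
  others <- do.call(rbind, rows)
  list(features = rbind(ref_fv, others),
       report = conservation_report(ref_fv, others, ...))
}
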