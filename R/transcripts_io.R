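# I/O layer: FASTA in/out, TIS-call tables, candidate tables (TSV/GFF3).
#
# Coordinate convention used throughout the package: 1-based, inclusive,
# on the mature mRNA. The internal sequence alphabet is RNA ({A,C,G,U,N},
# uppercase); DNA input is converted on ingest.

#' Normalize a raw nucleotide string to the internal RNA alphabet
#'
#' Uppercases, strips whitespace, converts T to U, and rejects anything
#' outside `{A,C,G,U,N}`.
#'
#' @param raw Character scalar, DNA or RNA, any case.
#' @return Character scalar over `{A,C,G,U,N}`.
#' @examples
#' normalize_alphabet("atgtt") # "AUGUU"
#' @export
normalize_alphabet <- function(raw) {
  if (!is_string(raw)) abort("sequence must be a single character string")
  s <- gsub("[ \t\r\n]", "", raw)
  if (nchar(s) == 0L) abort("sequence is empty after stripping whitespace")
  s <- chartr("T", "U", toupper(s))
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0L) {
    abort("illegal residue '%s' at offset %d", substr(s, bad, bad), bad)
  }
  s
}

#' Read an mRNA FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; sequences are
#' then normalized to the internal RNA alphabet, so the file may contain
#' DNA or RNA in any case.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description`, `seq`
#'   (one row per record, input order preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(0), description = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("[ \t].*$", "", headers)
  desc <- ifelse(grepl("[ \t]", headers),
                 sub("^[^ \t]+[ \t]+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort("duplicate FASTA id: %s", ids[duplicated(ids)][1L])
  }
  if (any(ids == "")) abort("FASTA record with empty id")
  seqs <- vapply(seq_along(set), function(i) {
    tryCatch(normalize_alphabet(as.character(set[[i]])),
             error = function(e) abort("record '%s': %s", ids[i], conditionMessage(e)))
  }, character(1))
  data.frame(id = ids, description = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records `data.frame` with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) && nzchar(records$description[i])) {
      paste0(" ", records$description[i])
    } else ""
    writeLines(paste0(">", records$id[i], desc), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a table of translation initiation site (TIS) calls
#'
#' The table emulates a curated ribosome-profiling TIS dataset: one row
#' per observed initiation event. The dialect is strict and defined by
#' this package (no community standard exists for TIS calls):
#' tab-separated with header
#' `transcript_id  pos  codon  init_score  is_canonical`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with typed columns; `pos` is the 1-based position
#'   of the first nucleotide of the start codon; `codon` one of
#'   AUG/CUG/GUG/ACG/AUA/AUU/AUC/UUG; `init_score` a non-negative
#'   initiation score; `is_canonical` logical.
#' @export
read_tis_table <- function(path) {
  if (!file.exists(path)) abort("TIS table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("transcript_id", "pos", "codon", "init_score", "is_canonical")
  missing <- setdiff(required, names(df))
  if (length(missing)) abort("TIS table is missing column(s): %s",
                             paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      codon = character(0), init_score = numeric(0),
                      is_canonical = logical(0), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) abort("TIS table line %d: non-integer pos '%s'",
                        which(is.na(pos))[1L] + 1L, df$pos[which(is.na(pos))[1L]])
  if (any(pos < 1L)) abort("TIS table line %d: pos < 1",
                           which(pos < 1L)[1L] + 1L)
  codon <- toupper(chartr("T", "U", df$codon))
  bad <- !codon %in% TIS_CODONS
  if (any(bad)) abort("TIS table line %d: unknown start codon '%s'",
                      which(bad)[1L] + 1L, df$codon[which(bad)[1L]])
  score <- suppressWarnings(as.numeric(df$init_score))
  bad_score <- is.na(score) & !toupper(trimws(df$init_score)) %in% c("NA", "")
  if (any(bad_score)) {
    abort("TIS table line %d: non-numeric init_score '%s'",
          which(bad_score)[1L] + 1L, df$init_score[which(bad_score)[1L]])
  }
  if (any(score < 0, na.rm = TRUE)) abort("TIS table line %d: negative init_score",
                                          which(score < 0)[1L] + 1L)
  canon <- tolower(df$is_canonical) %in% c("true", "t", "1", "yes")
  out <- data.frame(transcript_id = df$transcript_id, pos = pos, codon = codon,
                    init_score = score, is_canonical = canon,
                    stringsAsFactors = FALSE)
  dup <- tapply(out$is_canonical, out$transcript_id, sum)
  if (any(dup > 1L)) {
    abort("transcript '%s' has %d canonical TIS calls (at most one allowed)",
          names(dup)[dup > 1L][1L], max(dup))
  }
  out
}

CANDIDATE_COLUMNS <- c("transcript_id", "cTIS", "iuTIS", "iuSTOP_end", "ntTIS",
                       "class", "spacer_nt", "iuORF_len_codons",
                       "iu_kozak", "nt_kozak", "init_score")

empty_candidates <- function() {
  data.frame(transcript_id = character(0), cTIS = integer(0), iuTIS = integer(0),
             iuSTOP_end = integer(0), ntTIS = integer(0), class = character(0),
             spacer_nt = integer(0), iuORF_len_codons = integer(0),
             iu_kozak = character(0), nt_kozak = character(0),
             init_score = numeric(0), stringsAsFactors = FALSE)
}

sort_candidates <- function(candidates) {
  candidates[order(candidates$transcript_id, candidates$iuTIS), , drop = FALSE]
}

#' Write iuORF candidates as TSV or GFF3
#'
#' Output is deterministic for a fixed input: rows are sorted by
#' `transcript_id`, then `iuTIS`. GFF3 emits two features per candidate:
#' the iuORF interval (type `CDS`) and the truncated-proteoform TIS as a
#' 1-nt feature (type `TIS`); coordinates are 1-based inclusive on the
#' mRNA.
#'
#' @param candidates Candidate `data.frame` as produced by
#'   [screen_transcriptome()] (columns `transcript_id`, `cTIS`, `iuTIS`,
#'   `iuSTOP_end`, `ntTIS`, `class`, `spacer_nt`, `iuORF_len_codons`,
#'   `iu_kozak`, `nt_kozak`, `init_score`).
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(candidates))
  missing <- setdiff(CANDIDATE_COLUMNS, names(candidates))
  if (length(missing)) abort("candidates are missing column(s): %s",
                             paste(missing, collapse = ", "))
  candidates <- sort_candidates(candidates[, CANDIDATE_COLUMNS, drop = FALSE])
  if (format == "tsv") {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    score <- if (is.na(r$init_score)) "." else format(r$init_score)
    attrs <- sprintf(
      "ID=iuORF:%s:%d;class=%s;spacer_nt=%d;iuORF_len_codons=%d;iu_kozak=%s;nt_kozak=%s;cTIS=%d",
      r$transcript_id, r$iuTIS, r$class, r$spacer_nt, r$iuORF_len_codons,
      r$iu_kozak, r$nt_kozak, r$cTIS)
    lines <- c(lines,
      paste(r$transcript_id, "iuorfscan", "CDS", r$iuTIS, r$iuSTOP_end,
            score, "+", "0", attrs, sep = "\t"),
      paste(r$transcript_id, "iuorfscan", "TIS", r$ntTIS, r$ntTIS,
            ".", "+", ".",
            sprintf("ID=ntTIS:%s:%d;Parent=iuORF:%s:%d",
                    r$transcript_id, r$ntTIS, r$transcript_id, r$iuTIS),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate TSV written by [write_candidates()]
#'
#' @param path Path to the TSV file.
#' @return Candidate `data.frame`.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) abort("candidate table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(CANDIDATE_COLUMNS, names(df))
  if (length(missing)) abort("candidate table is missing column(s): %s",
                             paste(missing, collapse = ", "))
  for (col in c("cTIS", "iuTIS", "iuSTOP_end", "ntTIS", "spacer_nt",
                "iuORF_len_codons")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$init_score <- as.numeric(df$init_score)
  df[, CANDIDATE_COLUMNS, drop = FALSE]
}
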