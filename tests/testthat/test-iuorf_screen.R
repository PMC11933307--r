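mk_sorf <- function(start, stop_end, id = "t", score = NA_real_) {
  data.frame(transcript_id = id, start = as.integer(start),
             stop_end = as.integer(stop_end),
             len_codons = as.integer((stop_end - start + 1) / 3 - 1),
             frame = 1L, start_codon = "AUG", init_score = score,
             stringsAsFactors = FALSE)
}
mk_nt <- function(pos) data.frame(pos = as.integer(pos), codon = "AUG",
                                  init_score = 1, stringsAsFactors = FALSE)

test_that("spacer sign convention reproduces the worked-example distance", {
  expect_identical(spacer_nt(466, 480), 14L)
  expect_identical(spacer_nt(479, 480), 1L)
  expect_identical(spacer_nt(500, 480), -20L)
})

test_that("pair_and_classify applies the upstream/overlapping geometry filters", {
  p <- screen_params()
  up <- pair_and_classify(mk_sorf(359, 466), mk_nt(480), p, ctis = 141)
  expect_identical(up$class, "upstream")
  expect_identical(up$spacer_nt, 14L)

  ov <- pair_and_classify(mk_sorf(359, 486), mk_nt(480), p, ctis = 141)
  expect_identical(ov$class, "overlapping")
  expect_identical(ov$spacer_nt, -6L)

  # strict 30-nt bound: 30 qualifies, 31 does not
  expect_identical(pair_and_classify(mk_sorf(359, 450), mk_nt(480), p, 141)$class,
                   "upstream")
  expect_identical(nrow(pair_and_classify(mk_sorf(359, 449), mk_nt(480), p, 141)),
                   0L)
  # ntTIS 5' of the sORF start never pairs
  expect_identical(nrow(pair_and_classify(mk_sorf(359, 466), mk_nt(300), p, 141)),
                   0L)
  # nearest qualifying ntTIS wins
  two <- pair_and_classify(mk_sorf(359, 466), mk_nt(c(480, 492)), p, 141)
  expect_identical(two$ntTIS, 480L)
})

test_that("tie-break keeps the highest-scoring sORF, then spacer, then 5'-most", {
  # two planted-style sORFs in one transcript via a hand-built fixture:
  # take a generated upstream transcript and add a second, lower-scoring
  # TIS call that also forms a qualifying sORF
  g <- generate_transcript(plant_spec(spacer_nt = 14), seed = 12)
  seq <- g$record$seq
  truth <- g$truth$candidate
  # find another out-of-frame AUG-free position: fabricate a call at a
  # CUG-like near-cognate start that extends to a valid sORF
  can <- canonical_orf("x", g$truth$ctis, g$truth$cstop_end)
  frames <- (seq_len(nchar(seq)) - can$ctis) %% 3
  alt <- NULL
  for (p in (can$ctis + 1):(truth$ntTIS - 4)) {
    if (frames[p] == 0 || p == truth$iuTIS) next
    orf <- extend_orf(seq, p)
    if (is.null(orf) || orf$len_codons > 100 || orf$len_codons < 1) next
    cand <- pair_and_classify(orf, mk_nt(truth$ntTIS), ctis = can$ctis)
    if (nrow(cand)) { alt <- p; break }
  }
  expect_false(is.null(alt)) # near-cognate qualifying starts are abundant
  calls <- rbind(g$tis_calls,
                 data.frame(transcript_id = g$record$id, pos = alt,
                            codon = substr(seq, alt, alt + 2),
                            init_score = 99, is_canonical = FALSE))
  won <- screen_transcript(seq, calls, transcript_id = g$record$id)
  expect_identical(won$iuTIS, as.integer(alt)) # score 99 beats the planted 5
  calls$init_score[calls$pos == alt] <- truth$init_score # tie on score
  won2 <- screen_transcript(seq, calls, transcript_id = g$record$id)
  expect_identical(won2$iuTIS,
                   c(alt, truth$iuTIS)[which.min(abs(c(
                     spacer_nt(extend_orf(seq, alt)$stop_end, truth$ntTIS),
                     truth$spacer_nt)))])
})

test_that("transcripts without a canonical call are excluded and counted", {
  g <- generate_transcript(plant_spec(), seed = 31)
  calls <- g$tis_calls
  calls$is_canonical <- FALSE
  expect_identical(nrow(screen_transcript(g$record$seq, calls)), 0L)
  rep <- screen_transcriptome(g$record, calls)
  expect_identical(rep$n_with_canonical_tis, 0L)
  expect_identical(rep$n_candidates, 0L)
  # contradictory canonical flags are a hard error
  calls$is_canonical <- TRUE
  expect_error(screen_transcript(g$record$seq, calls), "multiple canonical")
})

test_that("screen_transcriptome recovers exactly the planted truth", {
  tx <- generate_transcriptome(60, seed = 8)
  rep <- screen_transcriptome(tx$transcripts, tx$tis_table)
  planted <- tx$truth[tx$truth$class != "none", ]
  expect_identical(rep$n_candidates, nrow(planted))
  expect_identical(rep$n_upstream, sum(planted$class == "upstream"))
  expect_identical(rep$n_overlapping, sum(planted$class == "overlapping"))
  expect_identical(rep$n_candidates, rep$n_upstream + rep$n_overlapping)
  m <- merge(rep$candidates, planted, by = "transcript_id")
  expect_identical(nrow(m), nrow(planted))
  expect_identical(m$iuTIS.x, m$iuTIS.y)
  expect_identical(m$ntTIS.x, m$ntTIS.y)
  expect_identical(m$class.x, m$class.y)
  expect_candidates_valid(rep$candidates, tx$transcripts)
})

test_that("screen handles empty TIS tables and unknown transcript ids", {
  tx <- generate_transcriptome(5, seed = 14)
  empty <- tx$tis_table[0, ]
  rep <- screen_transcriptome(tx$transcripts, empty)
  expect_identical(rep$n_candidates, 0L)
  expect_identical(rep$n_with_canonical_tis, 0L)
  alien <- tx$tis_table
  alien$transcript_id[1] <- "not_a_transcript"
  expect_warning(screen_transcriptome(tx$transcripts, alien), "unknown transcript")
})

test_that("shrinking either screen parameter never adds candidates", {
  tx <- generate_transcriptome(40, seed = 19)
  key <- function(df) paste(df$transcript_id, df$iuTIS, df$ntTIS)
  base <- screen_transcriptome(tx$transcripts, tx$tis_table,
                               screen_params(max_codons = 100,
                                             max_upstream_spacer_nt = 30))
  for (p in list(screen_params(max_codons = 20),
                 screen_params(max_upstream_spacer_nt = 10),
                 screen_params(max_codons = 20, max_upstream_spacer_nt = 5))) {
    shrunk <- screen_transcriptome(tx$transcripts, tx$tis_table, p)
    expect_true(all(key(shrunk$candidates) %in% key(base$candidates)))
    expect_lte(shrunk$n_candidates, base$n_candidates)
  }
})

test_that("de-novo mode finds the same planted geometry without scores", {
  g <- generate_transcript(plant_spec(klass = "overlapping"), seed = 55)
  cand <- screen_transcript(g$record$seq, g$tis_calls,
                            screen_params(mode = "de-novo"))
  expect_identical(cand$iuTIS, g$truth$candidate$iuTIS)
  expect_identical(cand$class, "overlapping")
  expect_true(is.na(cand$init_score))
})
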