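test_that("planted transcripts are deterministic per seed and certified", {
  g1 <- generate_transcript(plant_spec(), seed = 5)
  g2 <- generate_transcript(plant_spec(), seed = 5)
  g3 <- generate_transcript(plant_spec(), seed = 6)
  expect_identical(g1, g2)
  expect_false(identical(g1$record$seq, g3$record$seq))
  expect_true(g1$truth$certificate)
  # the certificate's own claim: only planted AUGs exist
  expect_identical(length(gregexpr("AUG", g1$record$seq)[[1]]), 3L)
})

test_that("plant-then-recover round trips for each class and geometry", {
  for (case in list(list(klass = "upstream", spacer = 14L),
                    list(klass = "upstream", spacer = 5L),
                    list(klass = "overlapping", spacer = NA))) {
    spec <- if (case$klass == "upstream") {
      plant_spec(klass = "upstream", spacer_nt = case$spacer,
                 iuORF_len_codons = 26L)
    } else {
      plant_spec(klass = "overlapping", overlap_nt = 9L)
    }
    g <- generate_transcript(spec, seed = 71)
    cand <- screen_transcript(g$record$seq, g$tis_calls,
                              transcript_id = g$record$id)
    expect_identical(nrow(cand), 1L)
    expect_identical(cand$class, case$klass)
    if (!is.na(case$spacer)) expect_identical(cand$spacer_nt, case$spacer)
    expect_identical(cand$iuTIS, g$truth$candidate$iuTIS)
    expect_identical(cand$iu_kozak, spec$iu_kozak_tier)
    expect_identical(cand$nt_kozak, spec$nt_kozak_tier)
  }
  # negative control: class "none" yields no candidate despite an
  # internal in-frame TIS decoy
  g0 <- generate_transcript(plant_spec(klass = "none"), seed = 72)
  expect_identical(nrow(screen_transcript(g0$record$seq, g0$tis_calls)), 0L)
})

test_that("unrealizable plant specifications fail loudly", {
  # spacer = 1 mod 3 cannot put the ntTIS in frame
  expect_error(generate_transcript(plant_spec(spacer_nt = 31L)),
               "geometrically impossible")
  expect_error(generate_transcript(plant_spec(klass = "overlapping",
                                              overlap_nt = 5L)),
               "geometrically impossible")
  # geometry larger than the transcript
  expect_error(generate_transcript(plant_spec(iuORF_len_codons = 150L,
                                              transcript_len = 400L)),
               "does not fit")
  expect_error(plant_spec(iu_kozak_tier = "fabulous"), "tiers")
})

test_that("generate_transcriptome keeps books and writes valid inputs", {
  d <- withr::local_tempdir()
  tx <- generate_transcriptome(25, class_mix = c(upstream = 0.3,
                                                 overlapping = 0.2,
                                                 none = 0.5),
                               seed = 7,
                               fasta_path = file.path(d, "t.fa"),
                               tis_path = file.path(d, "t.tis.tsv"),
                               truth_path = file.path(d, "t.truth.tsv"))
  expect_identical(nrow(tx$transcripts), 25L)
  expect_identical(sort(unique(tx$truth$class)) %in%
                     c("none", "overlapping", "upstream"), rep(TRUE, 3))
  # files re-read through the package's own readers
  back_fa <- read_fasta(file.path(d, "t.fa"))
  expect_identical(back_fa$seq, tx$transcripts$seq)
  back_tis <- read_tis_table(file.path(d, "t.tis.tsv"))
  expect_identical(back_tis, tx$tis_table)
  expect_error(generate_transcriptome(5, class_mix = c(upstream = 0.9)),
               "sum to 1")
  # n = 0: empty but valid outputs
  tx0 <- generate_transcriptome(0, seed = 1,
                                fasta_path = file.path(d, "e.fa"))
  expect_identical(nrow(tx0$transcripts), 0L)
  expect_identical(nrow(tx0$truth), 0L)
})

test_that("ortholog trios are deterministic and respect the divergence knob", {
  t1 <- generate_ortholog_trio(divergence = 0.1, seed = 2)
  t2 <- generate_ortholog_trio(divergence = 0.1, seed = 2)
  expect_identical(t1, t2)
  t0 <- generate_ortholog_trio(divergence = 0, seed = 2)
  expect_identical(t0$reference$seq, t0$others$seq[1])
  expect_identical(t0$reference$seq, t0$others$seq[2])
  # observed per-site divergence is near the requested rate
  n <- nchar(t1$reference$seq)
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, t1$reference$seq, t1$others$seq)
  expect_true(all(diffs / n > 0.04 & diffs / n < 0.16))
  expect_error(generate_ortholog_trio(divergence = 0.7), "divergence")
})

test_that("screen-ratio and Ct generators are deterministic and honest", {
  s1 <- generate_screen_ratios(seed = 4)
  s2 <- generate_screen_ratios(seed = 4)
  expect_identical(s1, s2)
  expect_identical(nrow(s1$table), 184L + 16L)
  expect_identical(length(s1$hit_labels), 8L)
  expect_true(all(s1$table$ratio > 0))
  s0 <- generate_screen_ratios(n_hits = 0, seed = 4)
  expect_identical(length(s0$hit_labels), 0L)
  expect_error(generate_screen_ratios(n = 5, n_hits = 6), "n_hits")

  c1 <- generate_ct_table(2, seed = 9)
  expect_identical(c1, generate_ct_table(2, seed = 9))
  # noiseless recovery is exact
  c0 <- generate_ct_table(3.5, noise_sd_cycles = 0, n_reps = 4, seed = 1)
  expect_equal(initiation_index(c0$records)$per_replicate, rep(3.5, 4),
               tolerance = 1e-12)
  expect_error(generate_ct_table(-1), "positive")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_transcript(plant_spec(), seed = 99))
  invisible(generate_screen_ratios(seed = 99))
  expect_identical(.Random.seed, before)
})
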