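test_that("pairwise identity handles the degenerate cases", {
  expect_identical(pairwise_identity("ACGU", "ACGU"), 1)
  expect_identical(pairwise_identity("AAAA", "CCCC"), 0)
  expect_identical(pairwise_identity("MKV", "MKV"), 1) # amino acids too
})

test_that("alignment score equals an independent memoized recursion", {
  withr::local_seed(501)
  for (i in 1:40) {
    a <- random_rna(sample(5:40, 1))
    b <- random_rna(sample(5:40, 1))
    aln <- align_pair(a, b)
    expect_identical(aln$score, oracle_nw_score(a, b))
    # reported identity is consistent with the returned alignment
    ca <- strsplit(aln$aligned[[1]], "")[[1]]
    cb <- strsplit(aln$aligned[[2]], "")[[1]]
    expect_identical(aln$identity, sum(ca == cb & ca != "-") / length(ca))
    expect_identical(gsub("-", "", aln$aligned[[1]]), a)
    expect_identical(gsub("-", "", aln$aligned[[2]]), b)
  }
})

test_that("closest-ortholog selection maximizes identity", {
  ref <- "AUGGCCGAUUACGGAUGCCGUAAAGGG"
  near <- chartr("G", "C", substr(ref, 1, 3))
  cands <- data.frame(
    id = c("paralog", "ortholog"),
    seq = c(paste0(near, substr(ref, 4, 20), "ACGUACGU"),
            paste0(substr(ref, 1, 24), "AAA")),
    stringsAsFactors = FALSE)
  expect_identical(select_closest_ortholog(ref, cands)$id, "ortholog")
  expect_identical(select_closest_ortholog(ref, cands[2, ])$id, "ortholog")
  expect_error(select_closest_ortholog(ref, cands[0, ]), "at least one")
  # synthetic trio: higher divergence loses
  trio <- generate_ortholog_trio(divergence = 0.05, seed = 6)
  far <- generate_ortholog_trio(divergence = 0.3, seed = 7)$others[1, ]
  far$id <- "decoy_paralog"
  pool <- rbind(trio$others[1, ], far)
  expect_identical(select_closest_ortholog(trio$reference$seq, pool)$id,
                   trio$others$id[1])
})

test_that("position projection maps through gaps and round-trips", {
  aln <- align_pair("ACGUACGUAC", "ACGACGUAC") # 1 deletion in b
  for (p in 1:10) {
    q <- project_position(aln, "a", p, "b")
    if (!is.na(q)) {
      expect_identical(project_position(aln, "b", q, "a"), p)
    }
  }
  # a 3-nt deletion 5' of the position shifts it by -3
  a <- paste0("AAACCCGGGUUU", "ACGUACGU")
  b <- paste0("AAACCC", "GGG", "ACGUACGU") # drop UUU
  aln2 <- align_pair(a, b)
  expect_identical(project_position(aln2, "a", 15, "b"), 12L)
  expect_error(project_position(aln2, "zz", 1, "b"), "not in alignment")
  # randomized indel fixtures
  withr::local_seed(502)
  for (i in 1:25) {
    x <- random_rna(60)
    keep <- sort(sample(60, 50))
    y <- paste(strsplit(x, "")[[1]][keep], collapse = "")
    alnr <- align_pair(x, y)
    for (p in sample(60, 10)) {
      q <- project_position(alnr, "a", p, "b")
      if (!is.na(q)) expect_identical(project_position(alnr, "b", q, "a"), p)
    }
  }
})

test_that("translate_orf uses the standard code and stops at the stop", {
  expect_identical(translate_orf("AUGAAAUGGUAA", 1), "MKW")
  expect_identical(translate_orf("AUGAANUGGUAA", 1), "MXW")
  expect_identical(translate_orf("AUGAAA", 1), "MK") # runs off the end
})

test_that("reference feature vector reproduces the candidate fields", {
  t6 <- trip6_like_transcript()
  cand <- screen_transcript(t6$record$seq, t6$tis_calls,
                            transcript_id = t6$record$id)
  fv <- feature_vector(t6$record$seq, cand$cTIS, cand$iuTIS, cand$ntTIS)
  expect_identical(fv$iuORF_len_codons, cand$iuORF_len_codons)
  expect_identical(fv$spacer_nt, cand$spacer_nt)
  expect_identical(fv$iu_context_tier, cand$iu_kozak)
  expect_identical(fv$nt_context_tier, cand$nt_kozak)
  expect_identical(fv$iu_start_codon, "AUG")
  expect_identical(fv$dist_cTIS_to_iuTIS, cand$iuTIS - cand$cTIS)
})

test_that("ortholog trios conserve geometry but not the sORF peptide", {
  trio <- generate_ortholog_trio(divergence = 0.12, seed = 23)
  res <- conserve_candidate(trio$reference$seq, trio$truth$candidate,
                            trio$others)
  expect_true(all(res$report$flags))
  expect_lt(res$report$sorf_peptide_identity, 1)
  # zero divergence: everything conserved, peptide identical
  trio0 <- generate_ortholog_trio(divergence = 0, seed = 23)
  res0 <- conserve_candidate(trio0$reference$seq, trio0$truth$candidate,
                             trio0$others)
  expect_true(all(res0$report$flags))
  expect_identical(res0$report$sorf_peptide_identity, 1)
  # permutation invariance in the non-reference species
  fv <- res$features
  rep_a <- conservation_report(fv[1, ], fv[2:3, ])
  rep_b <- conservation_report(fv[1, ], fv[3:2, ])
  expect_identical(rep_a$flags, rep_b$flags)
  expect_identical(rep_a$sorf_peptide_identity, rep_b$sorf_peptide_identity)
})

test_that("a missing anchor marks features absent, not an error", {
  fv <- feature_vector("ACGUACGUACGUACGU", ctis = 1, iutis = NA, nttis = 5,
                       species = "x")
  expect_identical(fv$iu_start_codon, "absent")
  expect_true(is.na(fv$iuORF_len_codons))
  ref <- feature_vector("AUGAAAUAGAUGAAAUAG", 1, 4, 10)
  rep <- conservation_report(ref, fv)
  expect_false(rep$flags[["iu_start_codon"]])
})

test_that("a planted spacer shift is reported in the species feature vector", {
  # build an ortholog by inserting 6 nt into the spacer region by hand
  g <- generate_transcript(plant_spec(spacer_nt = 14), seed = 61)
  cand <- g$truth$candidate
  seq <- g$record$seq
  cut <- cand$iuSTOP_end + 3
  shifted <- paste0(substr(seq, 1, cut), "CCCGCC",
                    substr(seq, cut + 1, nchar(seq)))
  aln <- align_pair(seq, shifted, "ref", "shifted")
  fv <- feature_vector(shifted,
                       project_position(aln, "ref", cand$cTIS, "shifted"),
                       project_position(aln, "ref", cand$iuTIS, "shifted"),
                       project_position(aln, "ref", cand$ntTIS, "shifted"),
                       species = "shifted")
  expect_identical(fv$spacer_nt, cand$spacer_nt + 6L)
})
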