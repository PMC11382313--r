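test_that("native/neo classification follows the iMet rule", {
  expect_equal(classify_native_or_neo(1, "MWSTK"), "native")
  expect_equal(classify_native_or_neo(2, "MASTK"), "native")
  expect_equal(classify_native_or_neo(2, "MWSTK"), "neo")
  expect_equal(classify_native_or_neo(3, "MASTK"), "neo")
  expect_equal(classify_native_or_neo(c(1, 2, 3), "MASTKW"),
               c("native", "native", "neo"))
})

test_that("acetylation classes partition by the Met context", {
  #           123456789
  s <- "MSAMTKWMDL"
  expect_equal(acetyl_class(1, s), "Ac_MX")    # acetylated iMet
  expect_equal(acetyl_class(2, s), "M_Ac_X")   # residue after excised Met
  expect_equal(acetyl_class(4, s), "Ac_MX")    # internal Met start
  expect_equal(acetyl_class(5, s), "M_Ac_X")
  expect_equal(acetyl_class(6, s), "Other")
  # every acetylated call lands in exactly one class
  set.seed(15)
  for (rep in 1:20) {
    s <- random_protein(30)
    cls <- acetyl_class(2:29, s)
    expect_true(all(cls %in% c("Ac_MX", "M_Ac_X", "Other")))
  }
})

test_that("second-residue frequencies split by iMet presence and sum to 1", {
  prot <- make_proteome(list(P1 = "MDSTKW", P2 = "MASTKW"))
  calls <- data.frame(accession = c("P1", "P2"), position = c(1L, 2L))
  freq <- second_residue_frequency(calls, prot)
  ret <- freq[freq$imet == "retained", ]
  expect_equal(ret$residue, "D")
  expect_equal(ret$frequency, 1.0)
  rem <- freq[freq$imet == "removed", ]
  expect_equal(rem$residue, "A")
  expect_equal(rem$frequency, 1.0)
  expect_equal(nrow(second_residue_frequency(calls[0, ], prot)), 0L)
  # frequencies within each split always sum to one
  sim <- generate_proteome(champ_sim_config(n_proteins = 50), seed = 23)
  tp <- sim$truth$proteins
  ac <- tp[tp$acetylated, ]
  calls <- data.frame(accession = ac$accession, position = ac$native_start)
  freq <- second_residue_frequency(calls, sim$proteome)
  for (sp in unique(freq$imet))
    expect_equal(sum(freq$frequency[freq$imet == sp]), 1.0)
})

test_that("a neo position matches a presequence end exactly at end + 1", {
  expect_true(match_cleavage(30, 29))
  expect_false(match_cleavage(25, 20))
  expect_true(match_cleavage(23, 22))
  expect_false(match_cleavage(30, NA))
  # exactly one neo position matches a given annotation
  expect_equal(sum(match_cleavage(1:100, 29)), 1L)
})

test_that("neo calls accumulate annotation and prediction flags", {
  features <- data.frame(
    accession = c("A1", "A2"),
    kind = c("signal_peptide", "transit_peptide"),
    start = 1L, end = c(18L, 47L), evidence = "unknown",
    stringsAsFactors = FALSE)
  predictions <- data.frame(
    accession = c("A1", "A2"),
    predictor = c("signal_predictor", "transit_predictor"),
    presequence_end = c(16L, 46L), stringsAsFactors = FALSE)
  calls <- data.frame(accession = c("A1", "A2", "A3"),
                      position = c(17L, 47L, 12L),
                      stringsAsFactors = FALSE)
  ann <- annotate_neo(calls, features, predictions, ragged_window = 3)
  # predictor matches at end + 1; the annotated span does not
  expect_true(ann$predicted_signal[1])
  expect_false(ann$uniprot_signal[1])
  expect_true(ann$near_native[1])       # 17 is 2 residues from 18 + 1
  expect_true(ann$predicted_transit[2])
  expect_false(ann$uniprot_transit[2])  # annotated end 47 implies start 48
  expect_false(ann$unmatched[2])
  expect_true(ann$unmatched[3])
  expect_equal(ann$distance_from_native, c(16L, 46L, 11L))
  # monotone: dropping predictions never removes an annotation flag
  ann0 <- annotate_neo(calls, features, NULL, ragged_window = 3)
  expect_true(all(ann$uniprot_signal >= ann0$uniprot_signal))
  expect_true(all(ann$uniprot_transit >= ann0$uniprot_transit))
  # exact annotation match carries the uniprot flag
  calls2 <- data.frame(accession = "A1", position = 19L)
  expect_true(annotate_neo(calls2, features)$uniprot_signal)
})

test_that("start codons classify as canonical, near-cognate or none", {
  cds <- paste0("ATG", "GCC", "CTG", "GGG", "TAA")  # M A L G *
  expect_equal(near_cognate_check(cds, 1, "Ac_MX"), "canonical_AUG")
  expect_equal(near_cognate_check(cds, 3, "Ac_MX"), "near_cognate:CUG")
  expect_equal(near_cognate_check(cds, 4, "Ac_MX"), "none")
  # M_Ac_X reads the codon of the excised Met one residue upstream
  expect_equal(near_cognate_check(cds, 4, "M_Ac_X"), "near_cognate:CUG")
  expect_equal(near_cognate_check(cds, 3, "Other"), "none")
  # the configured set is exactly the one-mismatch neighbours of ATG
  expect_length(NEAR_COGNATE_CODONS, 9L)
  expect_false("ATG" %in% NEAR_COGNATE_CODONS)
})

test_that("ladder detection finds maximal consecutive runs", {
  l <- detect_ladders(c(3, 4, 5, 9))
  expect_equal(nrow(l), 1L)
  expect_equal(l$start_position, 3L)
  expect_equal(l$length, 3L)
  expect_equal(nrow(detect_ladders(c(2, 4, 6))), 0L)
  expect_equal(nrow(detect_ladders(integer())), 0L)
  # duplicated positions collapse
  expect_equal(detect_ladders(c(3, 3, 4, 5))$length, 3L)
  # equals the brute-force run scan on random position sets
  set.seed(19)
  for (rep in 1:30) {
    p <- sample(1:40, sample(0:15, 1))
    runs <- oracle_runs(p, 3)
    got <- detect_ladders(p, 3)
    expect_equal(nrow(got), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(got$start_position[k], runs[[k]][1])
      expect_equal(got$end_position[k], runs[[k]][2])
    }
  }
  # per-protein wrapper assigns ids
  calls <- data.frame(accession = c("P1", "P1", "P1", "P2"),
                      position = c(5, 6, 7, 5))
  lad <- detect_ladders_by_protein(calls)
  expect_equal(lad$ladder_id, "P1:5-7")
})

test_that("position histogram reports the near-Nt fraction and residue 3", {
  h <- position_histogram(c(3, 3, 60))
  expect_equal(h$fraction_below_50, 2 / 3)
  expect_equal(h$count_at_3, 2L)
  expect_equal(sum(h$counts), 3L)
  h0 <- position_histogram(integer())
  expect_equal(sum(h0$counts), 0L)
  expect_equal(h0$count_at_3, 0L)
})
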