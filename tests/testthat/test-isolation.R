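test_that("Z counts the free alpha-amine and basic side chains", {
  expect_equal(charge_z("KASDF", "free"), list(Z = 2L, positions = c(0L, 1L)))
  expect_equal(charge_z("SEQWNC", "acetyl")$Z, 0L)
  expect_equal(charge_z("ASEQHWNC", "free"),
               list(Z = 2L, positions = c(0L, 5L)))
  # acetylation removes exactly the alpha-amine charge
  set.seed(5)
  for (rep in 1:20) {
    s <- random_protein(sample(5:30, 1))
    expect_equal(charge_z(s, "acetyl")$Z, charge_z(s, "free")$Z - 1L)
  }
})

test_that("charge proximity uses the separation threshold", {
  expect_true(is_proximal(c(0, 1)))
  expect_false(is_proximal(c(0, 5)))
  expect_false(is_proximal(c(0, 1), threshold = 0))
  expect_error(is_proximal(c(0, 1, 4)), "two charge positions")
})

test_that("CHAMP-N keeps weakly retained peptides and rejects proximal pairs", {
  pep <- data.frame(
    sequence = c("SEQWNC", "MASTDF", "KASDF", "ASEQHWNC", "AHSDF", "KRASDF"),
    nt_state = c("acetyl", "free", "free", "free", "free", "free"),
    stringsAsFactors = FALSE)
  dec <- select_champ_n(pep)
  # acetylated Z=0 and free Z=1 N-terminal peptides are isolated
  expect_true(dec$selected[1]); expect_equal(dec$reason[1], "z_le_1")
  expect_true(dec$selected[2])
  # internal LysargiNase peptide: alpha-amine + Nt Lys are proximal
  expect_false(dec$selected[3]); expect_equal(dec$reason[3], "z2_proximal")
  # distant His-containing Z=2 peptide is isolated
  expect_true(dec$selected[4]); expect_equal(dec$reason[4], "z2_distant")
  # proximal His (position 2) is retained
  expect_false(dec$selected[5])
  # Z = 3 never selected
  expect_false(dec$selected[6]); expect_equal(dec$reason[6], "z_ge_3")
  # restriction of the distant-charge rule to His-containing peptides
  lysdist <- data.frame(sequence = "ASEQKWNC", nt_state = "free")
  expect_true(select_champ_n(lysdist)$selected)
  expect_false(select_champ_n(lysdist, distant_his_only = TRUE)$selected)
})

test_that("CHAMP-NC selects only Z <= 1; free Nt tryptic peptides are lost", {
  pep <- data.frame(
    sequence = c("MASTDK", "MASTDR", "WSTQN", "AHSTDK"),
    nt_state = c("acetyl", "free", "free", "acetyl"),
    stringsAsFactors = FALSE)
  dec <- select_champ_nc(pep)
  expect_true(dec$selected[1])    # acetylated Nt ending in K: Z = 1
  expect_false(dec$selected[2])   # free Nt ending in R: Z = 2
  expect_true(dec$selected[3])    # protein-Ct peptide, no K/R/H: Z = 1
  expect_false(dec$selected[4])   # acetylated but His + Lys: Z = 2
  # no proximity clause: distant Z = 2 still rejected
  far <- data.frame(sequence = "AAAAAAAAAK", nt_state = "free")
  expect_false(select_champ_nc(far)$selected)
})

test_that("CHAMP-C keeps single-carboxylate C-termini and flags blind spots", {
  pep <- data.frame(
    sequence = c("Q", "AGE", "WSTE", "AGKRQ"),
    category = c("protein_ct", "internal", "protein_ct", "protein_ct"),
    stringsAsFactors = FALSE)
  dec <- select_champ_c(pep)
  expect_true(dec$selected[1])
  expect_false(dec$selected[2])
  expect_equal(dec$reason[2], "acidic_ct_retained")
  expect_false(dec$selected[3])
  expect_equal(dec$reason[3], "blind_spot_acidic_ct")
  expect_true(dec$selected[4])    # charge is irrelevant for MOLEX
})

test_that("acetylation never decreases the chance of SCX selection", {
  set.seed(9)
  for (rep in 1:50) {
    s <- random_protein(sample(5:25, 1))
    for (m in c("CHAMP_N", "CHAMP_NC")) {
      free <- select_peptides(data.frame(sequence = s, nt_state = "free"), m)
      ac <- select_peptides(data.frame(sequence = s, nt_state = "acetyl"), m)
      expect_true(ac$selected >= free$selected)
    }
  }
})

test_that("CHAMP-C selection ignores missed cleavages entirely", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_protein(sample(30:60, 1))
    d <- select_champ_c(digest(s, "v8", 2))
    last <- substr(d$sequence, nchar(d$sequence), nchar(d$sequence))
    expect_equal(d$selected, !last %in% c("D", "E"))
  }
})

test_that("selection equals exhaustive rule evaluation on random digests", {
  set.seed(21)
  for (rep in 1:15) {
    s <- random_protein(sample(20:60, 1))
    pep <- digest(s, "lysarginase", 2)
    pep$nt_state <- sample(c("free", "acetyl"), nrow(pep), replace = TRUE)
    dec <- select_champ_n(pep)
    for (i in seq_len(nrow(pep))) {
      cz <- charge_z(pep$sequence[i], pep$nt_state[i])
      want <- cz$Z <= 1L ||
        (cz$Z == 2L && abs(diff(cz$positions)) > 2L)
      expect_equal(dec$selected[i], want)
    }
    nc <- select_champ_nc(pep)
    for (i in seq_len(nrow(pep)))
      expect_equal(nc$selected[i],
                   charge_z(pep$sequence[i], pep$nt_state[i])$Z <= 1L)
  }
})

test_that("on a His-free protein CHAMP-N selects exactly the Nt peptides", {
  set.seed(31)
  aa_no_h <- setdiff(c("A", "C", "D", "E", "F", "G", "I", "K", "L", "M",
                       "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), NULL)
  for (rep in 1:20) {
    s <- random_protein(sample(20:60, 1), aa = aa_no_h)
    dec <- select_champ_n(digest(s, "lysarginase", 0))
    expect_equal(dec$selected, dec$category == "protein_nt")
  }
})

test_that("detectability window and theoretical coverage", {
  expect_false(detectable(3))
  expect_true(detectable(6) && detectable(45))
  expect_false(detectable(46))
  # a single protein whose Nt peptide is length 10 with Z = 1
  prot <- make_proteome(list(P1 = paste0("MASTWQNPLD", "KAAAAAA")))
  cov <- theoretical_coverage(prot, "CHAMP_N")
  expect_equal(cov$theoretical_terminal_peptides, 1L)
  expect_equal(cov$detectable_fraction, 1.0)
  # coverage equals brute-force enumeration over a synthetic proteome
  sim <- generate_proteome(champ_sim_config(n_proteins = 60), seed = 17)
  cov <- theoretical_coverage(sim$proteome, "CHAMP_C")
  manual <- vapply(names(sim$proteome$sequences), function(acc) {
    s <- sim$proteome$sequences[[acc]]
    d <- digest(s, "v8", 0)
    ct <- d[d$category == "protein_ct", ][1, ]
    last <- substr(ct$sequence, nchar(ct$sequence), nchar(ct$sequence))
    (!last %in% c("D", "E")) && nchar(ct$sequence) >= 6 &&
      nchar(ct$sequence) <= 45
  }, logical(1))
  expect_equal(cov$detectable_fraction, mean(manual))
})
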