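#' Configuration for the synthetic terminomics study generator
#'
#' Bundles every knob of the generator: proteome composition, planted
#' terminal features, neo-N-terminus mechanisms, the intensity model
#' and the missed-cleavage mix. Defaults describe a human-like cell
#' lysate: presequences of 10-50 residues, a 60/30/10 mix of 0/1/2
#' missed cleavages, log-normal MS intensities, and a 5% internal
#' (non-terminal) intensity share surviving isolation.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (residues).
#' @param residue_freq Named residue sampling frequencies (defaults to
#'   human-like composition).
#' @param p_signal,p_transit Probability that a protein carries a
#'   signal / transit peptide (mutually exclusive; signal drawn first).
#' @param presequence_length_range Length range of planted presequences.
#' @param p_predicted Probability that a presequence protein also has a
#'   predictor row (prediction end equals the planted end).
#' @param imet_rule Residues permitting initiator-Met removal.
#' @param p_acetyl_retained,p_acetyl_removed Nt-acetylation probability
#'   for proteins with the iMet retained (acetyl-Met) or removed
#'   (acetyl on residue 2).
#' @param p_ladder Probability of planting an exopeptidase ladder.
#' @param ladder_run_range Ladder run-length range (consecutive
#'   positions).
#' @param p_residue3 Probability of an over-cleavage neo-N-terminus at
#'   residue 3.
#' @param p_residue3_acetyl Probability that the residue-3 neo-terminus
#'   is acetylated.
#' @param p_near_cognate Probability of planting a near-cognate
#'   (CUG-initiated) internal start at an internal Met.
#' @param contamination_share Target internal-peptide share of total MS
#'   intensity after isolation (in \[0, 1\)).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param replicate_sdlog Log-scale SD of the per-replicate intensity
#'   jitter.
#' @param missed_weights Sampling weights for 0, 1, 2 missed cleavages.
#' @param n_replicates Replicates per method.
#' @param min_len,max_len Detectability window (residues).
#' @param proximity SCX charge-proximity threshold.
#' @return A list of class `champ_sim_config`.
#' @export
champ_sim_config <- function(n_proteins = 300L,
                             length_range = c(80L, 300L),
                             residue_freq = HUMAN_AA_FREQ,
                             p_signal = 0.12,
                             p_transit = 0.08,
                             presequence_length_range = c(10L, 50L),
                             p_predicted = 0.8,
                             imet_rule = IMET_REMOVABLE,
                             p_acetyl_retained = 0.5,
                             p_acetyl_removed = 0.7,
                             p_ladder = 0.05,
                             ladder_run_range = c(3L, 6L),
                             p_residue3 = 0.10,
                             p_residue3_acetyl = 0.17,
                             p_near_cognate = 0.02,
                             contamination_share = 0.05,
                             intensity_meanlog = log(1e6),
                             intensity_sdlog = 0.8,
                             replicate_sdlog = 0.1,
                             missed_weights = c(0.6, 0.3, 0.1),
                             n_replicates = 3L,
                             min_len = 6L,
                             max_len = 45L,
                             proximity = 2L) {
  cfg <- as.list(environment())
  probs <- c(p_signal, p_transit, p_predicted, p_acetyl_retained,
             p_acetyl_removed, p_ladder, p_residue3, p_residue3_acetyl,
             p_near_cognate, contamination_share)
  stopifnot(all(probs >= 0 & probs <= 1), p_signal + p_transit <= 1,
            contamination_share < 1,
            length(missed_weights) == 3L, all(missed_weights >= 0),
            n_proteins >= 1L, length_range[1] >= 30L)
  cfg$residue_freq <- residue_freq / sum(residue_freq)
  cfg$missed_weights <- missed_weights / sum(missed_weights)
  class(cfg) <- "champ_sim_config"
  cfg
}

#' Human-like amino-acid background frequencies
#' @export
HUMAN_AA_FREQ <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6,
                   H = 2.6, I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6,
                   P = 6.3, Q = 4.8, R = 5.6, S = 8.3, T = 5.4, V = 6.0,
                   W = 1.2, Y = 2.7) / 100

# most-frequent human codon per residue; deterministic back-translation
CODON_TABLE <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
                 G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
                 M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGG",
                 S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

back_translate <- function(sequence) {
  paste0(paste(CODON_TABLE[strsplit(sequence, "")[[1]]], collapse = ""),
         "TAA")
}

# sample one element of v (safe for length-one vectors)
sample1 <- function(v) v[sample.int(length(v), 1L)]

#' Generate a synthetic proteome with planted terminal features
#'
#' Builds a Met-initiated proteome with mutually exclusive signal or
#' transit presequences, iMet-removal and Nt-acetylation features,
#' planted neo-N-termini (presequence cleavage, exopeptidase ladders,
#' residue-3 over-cleavage, near-cognate internal starts) and a
#' consistent back-translated CDS in which near-cognate starts carry a
#' CTG codon at the planted Met. Every planted fact is exported in the
#' ground-truth tables. Seeded runs are reproducible.
#'
#' @param config A [champ_sim_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `champ_sim`: `proteome` (a
#'   `champ_proteome`), `cds` (named character), `predictions` (data
#'   frame), `truth` (list with `proteins` and `neo` data frames) and
#'   `config`.
#' @export
generate_proteome <- function(config = champ_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "champ_sim_config"))
  set.seed(seed)
  aa <- names(config$residue_freq)
  seqs <- character(config$n_proteins)
  acc <- sprintf("SYN%04d", seq_len(config$n_proteins))
  feat <- list(); pred <- list(); neo <- list()
  prot_truth <- data.frame(
    accession = acc, length = 0L, native_start = 1L,
    acetylated = FALSE, presequence = "none",
    presequence_end = NA_integer_, stringsAsFactors = FALSE)
  cds <- character(config$n_proteins)
  names(cds) <- acc

  for (i in seq_len(config$n_proteins)) {
    L <- sample1(config$length_range[1]:config$length_range[2])
    body <- sample(aa, L - 1L, replace = TRUE,
                   prob = config$residue_freq)
    s <- paste0("M", paste(body, collapse = ""))
    prot_truth$length[i] <- L

    # presequence (signal XOR transit), mature start must not be K/R so
    # the released neo-N-terminus is distinguishable from a digestion
    # product
    u <- stats::runif(1)
    pre_kind <- if (u < config$p_signal) "signal_peptide"
                else if (u < config$p_signal + config$p_transit)
                  "transit_peptide" else NA
    if (!is.na(pre_kind)) {
      rng <- config$presequence_length_range
      hi <- min(rng[2], L - config$max_len - 1L)
      if (hi >= rng[1]) {
        pe <- sample1(rng[1]:hi)
        for (try in 1:10) {
          if (!substr(s, pe + 1L, pe + 1L) %in% c("K", "R")) break
          pe <- sample1(rng[1]:hi)
        }
        if (!substr(s, pe + 1L, pe + 1L) %in% c("K", "R")) {
          feat[[length(feat) + 1L]] <- data.frame(
            accession = acc[i], kind = pre_kind, start = 1L, end = pe,
            evidence = "unknown", stringsAsFactors = FALSE)
          prot_truth$presequence[i] <- sub("_peptide", "", pre_kind)
          prot_truth$presequence_end[i] <- pe
          neo[[length(neo) + 1L]] <- data.frame(
            accession = acc[i], position = pe + 1L,
            mechanism = "presequence_cleavage", acetylated = FALSE,
            true_class = NA_character_, stringsAsFactors = FALSE)
          if (stats::runif(1) < config$p_predicted)
            pred[[length(pred) + 1L]] <- data.frame(
              accession = acc[i],
              predictor = ifelse(pre_kind == "signal_peptide",
                                 "signal_predictor", "transit_predictor"),
              presequence_end = pe, stringsAsFactors = FALSE)
        }
      }
    }

    has_pre <- prot_truth$presequence[i] != "none"
    # iMet removal and co-translational Nt-acetylation of the native
    # start (cytosolic proteins only; presequences are cleaved instead)
    r2 <- substr(s, 2L, 2L)
    removed <- r2 %in% config$imet_rule
    prot_truth$native_start[i] <- if (removed) 2L else 1L
    if (removed)
      feat[[length(feat) + 1L]] <- data.frame(
        accession = acc[i], kind = "imet_removed", start = 1L, end = 1L,
        evidence = "unknown", stringsAsFactors = FALSE)
    if (!has_pre) {
      p_ac <- if (removed) config$p_acetyl_removed
              else config$p_acetyl_retained
      if (stats::runif(1) < p_ac) {
        prot_truth$acetylated[i] <- TRUE
        st <- prot_truth$native_start[i]
        feat[[length(feat) + 1L]] <- data.frame(
          accession = acc[i], kind = "nt_acetyl", start = st, end = st,
          evidence = "unknown", stringsAsFactors = FALSE)
      }
    }

    # residue-3 over-cleavage by methionine aminopeptidase
    if (!has_pre && stats::runif(1) < config$p_residue3 &&
        !substr(s, 3L, 3L) %in% c("K", "R")) {
      ac3 <- stats::runif(1) < config$p_residue3_acetyl
      neo[[length(neo) + 1L]] <- data.frame(
        accession = acc[i], position = 3L, mechanism = "residue3",
        acetylated = ac3,
        true_class = if (!ac3) NA_character_
                     else if (substr(s, 3L, 3L) == "M") "Ac_MX"
                     else if (substr(s, 2L, 2L) == "M") "M_Ac_X"
                     else "Other",
        stringsAsFactors = FALSE)
    }

    # exopeptidase ladder: consecutive starts, all non-K/R so each rung
    # reads as a non-specific (neo) start
    if (stats::runif(1) < config$p_ladder) {
      run <- sample1(config$ladder_run_range[1]:config$ladder_run_range[2])
      for (s0 in 4:12) {
        rungs <- s0:(s0 + run - 1L)
        ok <- all(!strsplit(substr(s, s0, s0 + run - 1L), "")[[1]] %in%
                    c("K", "R")) && s0 + run - 1L + config$min_len <= L
        if (ok) {
          for (p in rungs)
            neo[[length(neo) + 1L]] <- data.frame(
              accession = acc[i], position = p, mechanism = "ladder",
              acetylated = FALSE, true_class = NA_character_,
              stringsAsFactors = FALSE)
          break
        }
      }
    }

    # near-cognate (CTG) internal initiation at an internal Met,
    # evidenced by co-translational acetylation of that Met
    near_pos <- NA_integer_
    if (stats::runif(1) < config$p_near_cognate) {
      mets <- which(strsplit(s, "")[[1]] == "M")
      mets <- mets[mets >= 10L & mets <= L - config$min_len]
      if (length(mets)) {
        near_pos <- if (length(mets) == 1L) mets else sample(mets, 1L)
        neo[[length(neo) + 1L]] <- data.frame(
          accession = acc[i], position = near_pos,
          mechanism = "near_cognate", acetylated = TRUE,
          true_class = "Ac_MX", stringsAsFactors = FALSE)
      }
    }

    seqs[i] <- s
    dna <- back_translate(s)
    if (!is.na(near_pos))
      substr(dna, 3L * near_pos - 2L, 3L * near_pos) <- "CTG"
    cds[i] <- dna
  }

  names(seqs) <- acc
  features <- if (length(feat)) do.call(rbind, feat) else empty_features()
  proteome <- structure(list(sequences = seqs,
                             features = validate_features(features, seqs)),
                        class = "champ_proteome")
  neo_df <- if (length(neo)) do.call(rbind, neo) else
    data.frame(accession = character(), position = integer(),
               mechanism = character(), acetylated = logical(),
               true_class = character(), stringsAsFactors = FALSE)
  neo_df <- neo_df[!duplicated(neo_df[c("accession", "position")]), ,
                   drop = FALSE]
  rownames(neo_df) <- NULL
  predictions <- if (length(pred)) do.call(rbind, pred) else
    data.frame(accession = character(), predictor = character(),
               presequence_end = integer(), stringsAsFactors = FALSE)
  structure(list(proteome = proteome, cds = cds,
                 predictions = predictions,
                 truth = list(proteins = prot_truth, neo = neo_df),
                 config = config),
            class = "champ_sim")
}

#' @export
print.champ_sim <- function(x, ...) {
  cat("champ_sim:", length(x$proteome$sequences), "proteins;",
      nrow(x$truth$neo), "planted neo-N-termini\n")
  if (nrow(x$truth$neo)) print(table(x$truth$neo$mechanism))
  invisible(x)
}

# first acceptable C-terminal boundary for a peptide starting at p:
# enzyme-specific end (or protein Ct), length within the window, at
# most `max_missed` spanned boundaries, and selected by the method rule
candidate_peptide <- function(s, p, sites, L, method, nt_mod, config) {
  ends <- c(sites[sites >= p + config$min_len - 1L &
                    sites <= p + config$max_len - 1L],
            if (L >= p + config$min_len - 1L && L <= p + config$max_len - 1L)
              L)
  for (e in ends) {
    m <- sum(sites > p - 1L & sites < e)
    if (m > 2L) next
    pep <- data.frame(sequence = substr(s, p, e), nt_state = nt_mod,
                      stringsAsFactors = FALSE)
    dec <- select_peptides(pep, method, proximity = config$proximity)
    if (dec$selected) return(list(start = p, end = e, missed = m))
  }
  NULL
}

#' Simulate an identified-peptide evidence table for one method
#'
#' Digests every protein with the method's enzyme, emits its terminal
#' peptide(s) at a missed-cleavage count drawn from the configured
#' 60/30/10 mix when the isolation rule selects them and the length is
#' within the detectability window, emits the planted neo-N-terminal
#' peptides the same way (CHAMP-N only, mirroring a semi-specific
#' N-terminal-free search), and adds a contamination sample of rejected
#' internal peptides sized so that the expected internal intensity
#' share equals `contamination_share`. Intensities are log-normal per
#' peptide; replicates jitter intensities only.
#'
#' @param sim A `champ_sim` from [generate_proteome()].
#' @param method `"CHAMP_N"`, `"CHAMP_NC"` or `"CHAMP_C"`.
#' @param seed Integer RNG seed.
#' @return List with `evidence` (data frame in the evidence-TSV schema)
#'   and `neo_status` (the planted-neo truth table with an `emitted`
#'   column; non-CHAMP-N methods emit no neo peptides).
#' @export
simulate_evidence <- function(sim, method = c("CHAMP_N", "CHAMP_NC",
                                              "CHAMP_C"),
                              seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(sim, "champ_sim"))
  config <- sim$config
  set.seed(seed)
  enz <- method_enzyme(method)
  seqs <- sim$proteome$sequences
  tp <- sim$truth$proteins
  rows <- list()
  pool_acc <- character(); pool_start <- integer(); pool_end <- integer()

  add_row <- function(acc, start, end, nt_mod) {
    rows[[length(rows) + 1L]] <<- data.frame(
      accession = acc, sequence = substr(seqs[[acc]], start, end),
      start = start, nt_mod = nt_mod, stringsAsFactors = FALSE)
  }

  emit_terminal <- function(acc, i, sites, L) {
    s <- seqs[[acc]]
    m <- sample(0:2, 1L, prob = config$missed_weights)
    if (method %in% c("CHAMP_N", "CHAMP_NC") &&
        tp$presequence[i] == "none") {
      st <- tp$native_start[i]
      nt_mod <- if (tp$acetylated[i]) "acetyl" else "free"
      up <- sites[sites >= st]
      en <- if (length(up) > m) up[m + 1L] else L
      if (detectable(en - st + 1L, config$min_len, config$max_len)) {
        pep <- data.frame(sequence = substr(s, st, en), nt_state = nt_mod,
                          stringsAsFactors = FALSE)
        if (select_peptides(pep, method,
                            proximity = config$proximity)$selected)
          add_row(acc, st, en, nt_mod)
      }
    }
    if (method %in% c("CHAMP_NC", "CHAMP_C")) {
      lo <- sites[sites < L]
      st <- if (length(lo) > m) lo[length(lo) - m] + 1L else 1L
      if (st > 1L &&
          detectable(L - st + 1L, config$min_len, config$max_len)) {
        pep <- data.frame(sequence = substr(s, st, L), nt_state = "free",
                          category = "protein_ct",
                          stringsAsFactors = FALSE)
        if (select_peptides(pep, method,
                            proximity = config$proximity)$selected)
          add_row(acc, st, L, "free")
      }
    }
  }

  neo_status <- sim$truth$neo
  neo_status$emitted <- FALSE

  for (i in seq_len(nrow(tp))) {
    acc <- tp$accession[i]
    s <- seqs[[acc]]
    L <- nchar(s)
    sites <- cleavage_sites(s, enz)
    emit_terminal(acc, i, sites, L)
    if (method == "CHAMP_N" && nrow(neo_status)) {
      idx <- which(neo_status$accession == acc)
      for (j in idx) {
        nm <- if (neo_status$acetylated[j]) "acetyl" else "free"
        cand <- candidate_peptide(s, neo_status$position[j], sites, L,
                                  method, nm, config)
        if (!is.null(cand)) {
          add_row(acc, cand$start, cand$end, nm)
          neo_status$emitted[j] <- TRUE
        }
      }
    }
    # rejected internal peptides: the contamination pool (0 missed)
    b <- c(0L, sites, L)
    if (length(b) > 3L) {
      st0 <- b[2:(length(b) - 2L)] + 1L
      en0 <- b[3:(length(b) - 1L)]
      keep <- detectable(en0 - st0 + 1L, config$min_len, config$max_len)
      if (any(keep)) {
        pool_acc <- c(pool_acc, rep(acc, sum(keep)))
        pool_start <- c(pool_start, st0[keep])
        pool_end <- c(pool_end, en0[keep])
      }
    }
  }

  terminal <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), sequence = character(),
               start = integer(), nt_mod = character(),
               stringsAsFactors = FALSE)

  # contamination sized so the expected internal intensity share is
  # contamination_share (intensities are iid across peptides)
  cshare <- config$contamination_share
  n_c <- round(cshare / (1 - cshare) * nrow(terminal))
  cont <- data.frame(accession = character(), sequence = character(),
                     start = integer(), nt_mod = character(),
                     stringsAsFactors = FALSE)
  if (n_c > 0L && length(pool_acc)) {
    pick <- sample(length(pool_acc), min(n_c, length(pool_acc)))
    cont <- data.frame(
      accession = pool_acc[pick],
      sequence = substring(seqs[pool_acc[pick]], pool_start[pick],
                           pool_end[pick]),
      start = pool_start[pick], nt_mod = "free",
      stringsAsFactors = FALSE)
  }
  pep <- rbind(terminal, cont)
  if (nrow(pep)) {
    base <- stats::rlnorm(nrow(pep), config$intensity_meanlog,
                          config$intensity_sdlog)
    ev <- list()
    for (r in seq_len(config$n_replicates)) {
      e <- pep
      e$intensity <- base * stats::rlnorm(nrow(pep), 0,
                                          config$replicate_sdlog)
      e$replicate <- r
      e$method <- method
      ev[[r]] <- e
    }
    evidence <- do.call(rbind, ev)
  } else {
    evidence <- data.frame(accession = character(), sequence = character(),
                           start = integer(), nt_mod = character(),
                           intensity = numeric(), replicate = integer(),
                           method = character(), stringsAsFactors = FALSE)
  }
  rownames(evidence) <- NULL
  list(evidence = evidence, neo_status = neo_status)
}

#' Write a full synthetic study to disk
#'
#' Writes `proteome.fasta`, `cds.fasta`, `features.tsv`,
#' `predictions.tsv`, one `evidence_<method>.tsv` per method and
#' `truth_proteins.tsv` / `truth_neo.tsv` into `dir`.
#'
#' @param sim A `champ_sim`.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the evidence simulation (one offset per
#'   method).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(sim, dir, seed = 1L) {
  stopifnot(inherits(sim, "champ_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(proteome = file.path(dir, "proteome.fasta"),
         cds = file.path(dir, "cds.fasta"),
         features = file.path(dir, "features.tsv"),
         predictions = file.path(dir, "predictions.tsv"),
         truth_proteins = file.path(dir, "truth_proteins.tsv"),
         truth_neo = file.path(dir, "truth_neo.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sim$proteome$sequences), p["proteome"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$cds), p["cds"])
  write_tsv(sim$proteome$features, p["features"])
  write_tsv(sim$predictions, p["predictions"])
  write_tsv(sim$truth$proteins, p["truth_proteins"])
  write_tsv(sim$truth$neo, p["truth_neo"])
  for (m in c("CHAMP_N", "CHAMP_NC", "CHAMP_C")) {
    res <- simulate_evidence(sim, m, seed = seed + match(m, c(
      "CHAMP_N", "CHAMP_NC", "CHAMP_C")))
    f <- file.path(dir, paste0("evidence_", m, ".tsv"))
    write_tsv(res$evidence, f)
    p[paste0("evidence_", m)] <- f
  }
  invisible(p)
}
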