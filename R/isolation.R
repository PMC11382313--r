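#' Peptide charge number Z at acidic pH
#'
#' Z counts the basic sites carrying a positive charge under acidic
#' conditions: the free alpha-amine (absent when the N-terminus is
#' acetylated) plus each Lys, Arg and His side chain. Charge positions
#' are reported as indices within the peptide, with 0 denoting the
#' alpha-amine at residue 1.
#'
#' @param sequence Peptide amino-acid string.
#' @param nt_state `"free"` or `"acetyl"`.
#' @return List with `Z` (integer) and `positions` (integer vector).
#' @examples
#' charge_z("KASDF", "free")     # Z = 2, positions 0, 1
#' charge_z("SEQWNC", "acetyl")  # Z = 0
#' @export
charge_z <- function(sequence, nt_state = c("free", "acetyl")) {
  nt_state <- match.arg(nt_state)
  res <- strsplit(sequence, "")[[1]]
  side <- which(res %in% c("K", "R", "H"))
  positions <- if (nt_state == "free") c(0L, side) else side
  list(Z = length(positions), positions = as.integer(positions))
}

#' Are two charge sites in close proximity?
#'
#' Under the charge/orientation retention model, a peptide carrying two
#' positive charges is strongly retained on SCX when the charges sit
#' close together, and only weakly when they are far apart. The
#' alpha-amine (position 0) and a residue-1 side chain differ by 1.
#'
#' @param positions Integer vector of exactly two charge positions.
#' @param threshold Maximum separation still counted as proximal
#'   (default 2).
#' @return `TRUE` if the separation is at most `threshold`.
#' @export
is_proximal <- function(positions, threshold = 2L) {
  if (length(positions) != 2L)
    stop("is_proximal() requires exactly two charge positions, got ",
         length(positions))
  abs(diff(as.integer(positions))) <= threshold
}

#' Per-method terminal-peptide isolation decisions
#'
#' Applies the retention model of the three isolation chemistries to a
#' peptide table (as produced by [digest()], [semi_specific_nt_free()]
#' or an evidence table carrying `sequence` and `nt_mod`):
#'
#' * **CHAMP-N** (LysargiNase digest, SCX): selected when `Z <= 1`, or
#'   when `Z == 2` with the two charges at distant positions (beyond
#'   `proximity`). Internal LysargiNase peptides start with Lys/Arg, so
#'   their alpha-amine and N-terminal side chain form a proximal charge
#'   pair and they are retained (rejected). `Z >= 3` is never selected.
#' * **CHAMP-NC** (tryptic digest, SCX): selected when `Z <= 1` —
#'   acetylated N-terminal and protein C-terminal peptides; free
#'   N-terminal tryptic peptides carry `Z = 2` and are not isolated.
#' * **CHAMP-C** (V8 digest, MOLEX): selected when the peptide's
#'   C-terminal residue is not Asp/Glu, i.e. it carries a single
#'   C-terminal carboxylate. Non-C-terminal V8 peptides end in Asp/Glu,
#'   chelate the metal oxide and are retained; protein C-terminal
#'   peptides that happen to end in Asp/Glu are a blind spot and are
#'   flagged `blind_spot_acidic_ct`.
#'
#' @param peptides Data frame with at least `sequence`; optional
#'   `nt_state` or `nt_mod` (default `"free"`) and `category`.
#' @param method `"CHAMP_N"`, `"CHAMP_NC"` or `"CHAMP_C"`.
#' @param proximity Proximity threshold for the Z = 2 rule (CHAMP-N).
#' @param distant_his_only If `TRUE`, restrict the Z = 2 distant-charge
#'   acceptance to His-containing peptides.
#' @return The input with columns `Z`, `proximal`, `selected`, `reason`
#'   appended.
#' @export
select_peptides <- function(peptides,
                            method = c("CHAMP_N", "CHAMP_NC", "CHAMP_C"),
                            proximity = 2L, distant_his_only = FALSE) {
  method <- match.arg(method)
  n <- nrow(peptides)
  nt <- peptides$nt_state
  if (is.null(nt)) nt <- peptides$nt_mod
  if (is.null(nt)) nt <- rep("free", n)
  Z <- integer(n); proximal <- rep(NA, n)
  selected <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    cz <- charge_z(peptides$sequence[i], nt[i])
    Z[i] <- cz$Z
    if (method == "CHAMP_C") {
      last <- substr(peptides$sequence[i], nchar(peptides$sequence[i]),
                     nchar(peptides$sequence[i]))
      if (!last %in% c("D", "E")) {
        selected[i] <- TRUE; reason[i] <- "ct_no_acidic_end"
      } else {
        selected[i] <- FALSE
        ct <- !is.null(peptides$category) &&
          peptides$category[i] == "protein_ct"
        reason[i] <- if (ct) "blind_spot_acidic_ct" else "acidic_ct_retained"
      }
      next
    }
    if (cz$Z == 2L) proximal[i] <- is_proximal(cz$positions, proximity)
    if (method == "CHAMP_N") {
      if (cz$Z <= 1L) {
        selected[i] <- TRUE; reason[i] <- "z_le_1"
      } else if (cz$Z == 2L && !proximal[i] &&
                 (!distant_his_only ||
                    grepl("H", peptides$sequence[i], fixed = TRUE))) {
        selected[i] <- TRUE; reason[i] <- "z2_distant"
      } else {
        selected[i] <- FALSE
        reason[i] <- if (cz$Z == 2L) "z2_proximal" else "z_ge_3"
      }
    } else {                      # CHAMP_NC
      if (cz$Z <= 1L) {
        selected[i] <- TRUE; reason[i] <- "acetyl_or_ct_plus1"
      } else {
        selected[i] <- FALSE; reason[i] <- "z_ge_2"
      }
    }
  }
  peptides$Z <- Z
  peptides$proximal <- proximal
  peptides$selected <- selected
  peptides$reason <- reason
  peptides
}

#' @rdname select_peptides
#' @export
select_champ_n <- function(peptides, proximity = 2L,
                           distant_his_only = FALSE)
  select_peptides(peptides, "CHAMP_N", proximity, distant_his_only)

#' @rdname select_peptides
#' @export
select_champ_nc <- function(peptides)
  select_peptides(peptides, "CHAMP_NC")

#' @rdname select_peptides
#' @export
select_champ_c <- function(peptides)
  select_peptides(peptides, "CHAMP_C")

method_enzyme <- function(method) {
  switch(method,
         CHAMP_N = "lysarginase",
         CHAMP_NC = "trypsin",
         CHAMP_C = "v8",
         stop("unknown method: ", method))
}

#' MS-detectability length window
#'
#' Terminal peptides outside a length window are effectively invisible
#' to the LC/MS/MS workflow — too short to be matched confidently, too
#' long to ionize and fragment well. The default window of 6 to 45
#' residues reflects common search practice.
#'
#' @param length Integer vector of peptide lengths.
#' @param min_len,max_len Inclusive bounds.
#' @return Logical vector.
#' @export
detectable <- function(length, min_len = 6L, max_len = 45L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  length >= min_len & length <= max_len
}

#' Theoretical per-method terminome coverage of a proteome
#'
#' For each protein, takes its terminal peptide(s) under the method's
#' enzyme at zero missed cleavages — the N-terminal peptide for
#' CHAMP-N, both terminal peptides for CHAMP-NC, the C-terminal peptide
#' for CHAMP-C — applies the isolation rule and the detectability
#' window, and reports which termini are theoretically observable. The
#' N-terminal peptide is taken acetylated when the proteome annotates
#' `nt_acetyl` (or always for CHAMP-NC free-Nt rejection to be
#' meaningful, the annotation decides).
#'
#' @param proteome A `champ_proteome`.
#' @param method Method id.
#' @param proximity,min_len,max_len Rule parameters.
#' @return A list of class `champ_coverage`: `method`,
#'   `theoretical_terminal_peptides`, `detectable_fraction`, and a
#'   per-terminus data frame `flags` (`accession`, `terminus`,
#'   `length`, `selected`, `detectable`, `observable`, `reason`).
#' @export
theoretical_coverage <- function(proteome,
                                 method = c("CHAMP_N", "CHAMP_NC",
                                            "CHAMP_C"),
                                 proximity = 2L, min_len = 6L,
                                 max_len = 45L) {
  method <- match.arg(method)
  stopifnot(inherits(proteome, "champ_proteome"))
  enz <- method_enzyme(method)
  acetyl_acc <- unique(
    proteome$features$accession[proteome$features$kind == "nt_acetyl"])
  rows <- list()
  for (acc in names(proteome$sequences)) {
    s <- proteome$sequences[[acc]]
    d <- digest(s, enz, max_missed = 0L, accession = acc)
    want <- if (method == "CHAMP_N") "protein_nt"
            else if (method == "CHAMP_C") "protein_ct"
            else c("protein_nt", "protein_ct")
    term <- d[d$category %in% want | (method != "CHAMP_C" &
              d$start == 1L), , drop = FALSE]
    term <- term[!duplicated(term[c("start", "end")]), , drop = FALSE]
    if (nrow(term) == 0L) next
    term$nt_state <- ifelse(term$start == 1L & acc %in% acetyl_acc,
                            "acetyl", "free")
    dec <- select_peptides(term, method, proximity = proximity)
    dec$terminus <- ifelse(dec$category == "protein_ct", "Ct", "Nt")
    dec$length <- nchar(dec$sequence)
    dec$detectable <- detectable(dec$length, min_len, max_len)
    dec$observable <- dec$selected & dec$detectable
    rows[[acc]] <- dec[, c("accession", "terminus", "length", "selected",
                           "detectable", "observable", "reason")]
  }
  flags <- do.call(rbind, rows)
  rownames(flags) <- NULL
  structure(list(method = method,
                 theoretical_terminal_peptides = nrow(flags),
                 detectable_fraction = mean(flags$observable),
                 flags = flags),
            class = "champ_coverage")
}

#' @export
print.champ_coverage <- function(x, ...) {
  cat("Theoretical", x$method, "terminome coverage:\n")
  cat("  terminal peptides:", x$theoretical_terminal_peptides, "\n")
  cat(sprintf("  observable (selected & detectable): %.1f%%\n",
              100 * x$detectable_fraction))
  invisible(x)
}
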