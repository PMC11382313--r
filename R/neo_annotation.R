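#' Classify an identified N-terminal peptide as native or neo
#'
#' Native when the peptide starts at residue 1, or at residue 2 of a
#' Met-initiated protein whose second residue permits initiator-Met
#' removal; every other start is a neo-N-terminus (from endogenous
#' proteolysis or an alternative translation initiation site).
#'
#' @param start 1-based start position(s) in the protein.
#' @param sequence Protein amino-acid string.
#' @param imet_rule Residues permitting iMet removal.
#' @return Character vector `"native"`/`"neo"`.
#' @export
classify_native_or_neo <- function(start, sequence,
                                   imet_rule = IMET_REMOVABLE) {
  vapply(start, function(s)
    if (is_native_start(s, sequence, imet_rule)) "native" else "neo",
    character(1))
}

#' Acetylation class of an Nt-acetylated peptide
#'
#' `Ac_MX` when the acetylated residue (at the peptide start) is Met —
#' acetylation on a retained (initiator) methionine; `M_Ac_X` when the
#' residue immediately preceding the start is Met — acetylation on the
#' residue adjacent to an excised Met; `Other` when there is no Met at
#' either position. Because Nt-acetylation is almost always
#' co-translational, an acetylated neo-N-terminus of class `Ac_MX` or
#' `M_Ac_X` is evidence of a translation initiation event.
#'
#' @param start 1-based acetylated start position(s).
#' @param sequence Protein amino-acid string.
#' @return Character vector of classes.
#' @export
acetyl_class <- function(start, sequence) {
  vapply(start, function(p) {
    if (substr(sequence, p, p) == "M") return("Ac_MX")
    if (p >= 2L && substr(sequence, p - 1L, p - 1L) == "M") return("M_Ac_X")
    "Other"
  }, character(1))
}

#' Second-residue frequencies of acetylated N-termini
#'
#' Tabulates the amino-acid frequency at the second residue of the
#' translated form (the residue adjacent to the initiator Met),
#' separately for calls with the iMet retained (`Ac_MX`: second residue
#' at start + 1) and removed (`M_Ac_X`: the acetylated residue itself).
#' `Other` calls have no defined initiator Met and are excluded.
#'
#' @param calls Data frame with `accession` and `position` (acetylated
#'   start) columns.
#' @param proteome A `champ_proteome`.
#' @return Data frame with columns `residue`, `imet` (`"retained"` /
#'   `"removed"`), `count`, `frequency`; frequencies within each split
#'   sum to 1.
#' @export
second_residue_frequency <- function(calls, proteome) {
  out <- data.frame(residue = character(), imet = character(),
                    count = integer(), frequency = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(out)
  res <- character(); split <- character()
  for (i in seq_len(nrow(calls))) {
    s <- protein_sequence(proteome, calls$accession[i])
    p <- calls$position[i]
    cls <- acetyl_class(p, s)
    if (cls == "Ac_MX" && p + 1L <= nchar(s)) {
      res <- c(res, substr(s, p + 1L, p + 1L)); split <- c(split, "retained")
    } else if (cls == "M_Ac_X") {
      res <- c(res, substr(s, p, p)); split <- c(split, "removed")
    }
  }
  if (!length(res)) return(out)
  for (sp in unique(split)) {
    tab <- table(factor(res[split == sp], levels = AA20))
    keep <- tab > 0L
    out <- rbind(out, data.frame(residue = names(tab)[keep], imet = sp,
                                 count = as.integer(tab[keep]),
                                 frequency = as.numeric(tab[keep] / sum(tab)),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Does a neo-N-terminus match a presequence cleavage site?
#'
#' A signal or transit peptide spanning residues 1..end releases a
#' mature protein starting at end + 1, so a neo-N-terminal position
#' matches exactly when `neo_position == presequence_end + 1`.
#'
#' @param neo_position 1-based neo-N-terminal position(s).
#' @param presequence_end 1-based presequence end(s); `NA` gives `FALSE`.
#' @return Logical vector.
#' @examples
#' match_cleavage(30, 29)  # TRUE
#' match_cleavage(25, 20)  # FALSE
#' @export
match_cleavage <- function(neo_position, presequence_end) {
  stopifnot(all(neo_position >= 1L, na.rm = TRUE))
  !is.na(presequence_end) & !is.na(neo_position) &
    neo_position == presequence_end + 1L
}

#' Annotate neo-N-terminal calls against annotated and predicted
#' presequence cleavage sites
#'
#' Each neo call accumulates match flags: `uniprot_signal` /
#' `uniprot_transit` when it exactly matches an annotated
#' signal/transit span end + 1; `predicted_signal` /
#' `predicted_transit` when it matches a predictor's cleavage end + 1.
#' A call landing within `ragged_window` residues of an annotated
#' cleavage position without matching it exactly is flagged
#' `near_native` for review (ragged or mis-annotated cleavage); calls
#' matching nothing are `unmatched`. Adding predictions never removes
#' an annotation flag.
#'
#' @param calls Data frame with `accession`, `position` and optionally
#'   `nt_mod` columns (one row per distinct neo-N-terminus).
#' @param features Feature data frame as in a `champ_proteome`
#'   (`signal_peptide` / `transit_peptide` rows are used).
#' @param predictions Optional prediction data frame from
#'   [read_predictions()] (both predictor kinds may be row-bound).
#' @param ragged_window Half-width of the review window (default 3).
#' @return `calls` with logical columns `uniprot_signal`,
#'   `uniprot_transit`, `predicted_signal`, `predicted_transit`,
#'   `near_native`, `unmatched`, the integer `distance_from_native`
#'   (position − 1) and a collapsed `match_status` string.
#' @export
annotate_neo <- function(calls, features, predictions = NULL,
                         ragged_window = 3L) {
  n <- nrow(calls)
  for (col in c("uniprot_signal", "uniprot_transit", "predicted_signal",
                "predicted_transit", "near_native"))
    calls[[col]] <- logical(n)
  feat_end <- function(acc, kind) {
    f <- features[features$accession == acc & features$kind == kind, ,
                  drop = FALSE]
    if (nrow(f)) f$end[1] else NA_integer_
  }
  pred_end <- function(acc, kind) {
    if (is.null(predictions)) return(NA_integer_)
    p <- predictions[predictions$accession == acc &
                       predictions$predictor == kind, , drop = FALSE]
    if (nrow(p)) p$presequence_end[1] else NA_integer_
  }
  for (i in seq_len(n)) {
    acc <- calls$accession[i]; pos <- calls$position[i]
    se <- feat_end(acc, "signal_peptide")
    te <- feat_end(acc, "transit_peptide")
    calls$uniprot_signal[i] <- isTRUE(match_cleavage(pos, se))
    calls$uniprot_transit[i] <- isTRUE(match_cleavage(pos, te))
    calls$predicted_signal[i] <-
      isTRUE(match_cleavage(pos, pred_end(acc, "signal_predictor")))
    calls$predicted_transit[i] <-
      isTRUE(match_cleavage(pos, pred_end(acc, "transit_predictor")))
    for (e in c(se, te)) {
      if (!is.na(e) && pos != e + 1L && abs(pos - (e + 1L)) <= ragged_window)
        calls$near_native[i] <- TRUE
    }
  }
  flags <- c("uniprot_signal", "uniprot_transit", "predicted_signal",
             "predicted_transit", "near_native")
  calls$unmatched <- rowSums(as.matrix(calls[flags])) == 0L
  calls$distance_from_native <- calls$position - 1L
  calls$match_status <- vapply(seq_len(n), function(i) {
    on <- c(flags, "unmatched")[c(as.logical(unlist(calls[i, flags])),
                                  calls$unmatched[i])]
    paste(on, collapse = ";")
  }, character(1))
  calls
}

#' Default near-cognate start codon set
#'
#' The nine codons one nucleotide away from ATG, all of which can
#' initiate translation at low efficiency (CUG being the most active).
#' @export
NEAR_COGNATE_CODONS <- c("CTG", "GTG", "TTG", "ATA", "ATC", "ATT",
                         "ACG", "AAG", "AGG")

#' Check the start codon underlying an acetylated neo-N-terminus
#'
#' For an acetylated neo-N-terminus of class `Ac_MX` the putative
#' initiator Met is at the call position itself; for `M_Ac_X` it is the
#' excised Met at position − 1. The codon at that residue is read from
#' the coding sequence: `ATG` is a canonical start, a codon in
#' `near_cognate_set` is a near-cognate start candidate (reported in
#' RNA alphabet, e.g. `near_cognate:CUG`), anything else is `none`.
#'
#' @param cds Coding DNA string for the protein (codon i at nucleotides
#'   `3i - 2 .. 3i`).
#' @param position 1-based acetylated call position.
#' @param class Acetylation class from [acetyl_class()] (`Other` gives
#'   `"none"`).
#' @param near_cognate_set Codon set, default [NEAR_COGNATE_CODONS].
#' @return One of `"canonical_AUG"`, `"near_cognate:<codon>"`, `"none"`.
#' @export
near_cognate_check <- function(cds, position, class,
                               near_cognate_set = NEAR_COGNATE_CODONS) {
  if (!class %in% c("Ac_MX", "M_Ac_X")) return("none")
  p <- if (class == "Ac_MX") position else position - 1L
  stopifnot(p >= 1L, 3L * p <= nchar(cds))
  codon <- toupper(substr(cds, 3L * p - 2L, 3L * p))
  if (codon == "ATG") return("canonical_AUG")
  if (codon %in% near_cognate_set)
    return(paste0("near_cognate:", gsub("T", "U", codon)))
  "none"
}

#' Detect exopeptidase ladders among neo-N-terminal positions
#'
#' A ladder is a maximal run of strictly consecutive neo start
#' positions on one protein — the signature of an exopeptidase shaving
#' residues off one at a time. Runs shorter than `min_run` (default 3,
#' to distinguish a ladder from a single ragged pair) are ignored.
#'
#' @param positions Integer vector of neo start positions for one
#'   protein (deduplicated internally).
#' @param min_run Minimum run length.
#' @return Data frame with one row per ladder: `start_position`,
#'   `end_position`, `length`.
#' @examples
#' detect_ladders(c(3, 4, 5, 9))  # one ladder 3..5
#' @export
detect_ladders <- function(positions, min_run = 3L) {
  stopifnot(min_run >= 1L)
  p <- sort(unique(as.integer(positions)))
  out <- data.frame(start_position = integer(), end_position = integer(),
                    length = integer())
  if (!length(p)) return(out)
  run_start <- p[1]; prev <- p[1]
  flush <- function(out, s, e) {
    if (e - s + 1L >= min_run)
      rbind(out, data.frame(start_position = s, end_position = e,
                            length = e - s + 1L))
    else out
  }
  for (x in p[-1]) {
    if (x != prev + 1L) {
      out <- flush(out, run_start, prev)
      run_start <- x
    }
    prev <- x
  }
  flush(out, run_start, prev)
}

#' Ladders per protein across a call table
#'
#' @param calls Data frame with `accession` and `position`.
#' @param min_run Minimum run length.
#' @return Data frame with `accession`, `start_position`,
#'   `end_position`, `length`, `ladder_id`.
#' @export
detect_ladders_by_protein <- function(calls, min_run = 3L) {
  out <- list()
  for (acc in unique(calls$accession)) {
    l <- detect_ladders(calls$position[calls$accession == acc], min_run)
    if (nrow(l)) out[[acc]] <- cbind(accession = acc, l)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(accession = character(), start_position = integer(),
                      end_position = integer(), length = integer(),
                      ladder_id = character()))
  res$ladder_id <- paste0(res$accession, ":", res$start_position, "-",
                          res$end_position)
  rownames(res) <- NULL
  res
}

#' Histogram of neo-N-terminal distances from the native start
#'
#' @param positions Integer neo start positions (distance from the
#'   native N-terminus is position − 1).
#' @param breaks Histogram breaks over positions, as for [hist()]
#'   (default bins of width 10 covering the data).
#' @return List of class `champ_position_hist` with `counts`, `breaks`,
#'   `fraction_below_50` (fraction of calls at position < 50) and
#'   `count_at_3` (calls starting exactly at residue 3).
#' @export
position_histogram <- function(positions, breaks = NULL) {
  positions <- as.integer(positions)
  if (!length(positions)) {
    return(structure(list(counts = integer(), breaks = numeric(),
                          fraction_below_50 = NA_real_,
                          count_at_3 = 0L),
                     class = "champ_position_hist"))
  }
  if (is.null(breaks))
    breaks <- seq(0, 10 * ceiling(max(positions) / 10), by = 10)
  h <- graphics::hist(positions, breaks = breaks, plot = FALSE)
  structure(list(counts = h$counts, breaks = h$breaks,
                 fraction_below_50 = mean(positions < 50L),
                 count_at_3 = sum(positions == 3L)),
            class = "champ_position_hist")
}

#' @export
print.champ_position_hist <- function(x, ...) {
  cat("Neo-N-terminal position histogram\n")
  if (length(x$counts)) {
    cat(sprintf("  fraction at position < 50: %.3f\n", x$fraction_below_50))
    cat("  calls at position 3:", x$count_at_3, "\n")
  } else cat("  (no calls)\n")
  invisible(x)
}
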