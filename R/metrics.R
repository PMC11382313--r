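#' Intensity-based terminal-peptide selectivity
#'
#' Selectivity (%) is the summed MS signal intensity of the terminal
#' peptides divided by that of all identified peptides, times 100.
#' Entries without an intensity are excluded from both sums, so missing
#' values never dilute the estimate. Which peptides count as terminal
#' depends on the method: N-terminal for CHAMP-N, N- or C-terminal for
#' CHAMP-NC, C-terminal for CHAMP-C.
#'
#' @param intensity Numeric intensities (may contain `NA`).
#' @param terminal Logical: is each entry a terminal peptide?
#' @return Percentage in \[0, 100\] (`NA` if no usable intensity).
#' @examples
#' selectivity(c(90, 5, 5), c(TRUE, TRUE, FALSE))  # 95
#' @export
selectivity <- function(intensity, terminal) {
  stopifnot(length(intensity) == length(terminal))
  ok <- !is.na(intensity)
  if (!any(ok)) return(NA_real_)
  100 * sum(intensity[ok & terminal]) / sum(intensity[ok])
}

#' Whether each evidence entry is a terminal peptide for its method
#'
#' For CHAMP-N an entry counts as an N-terminal-class peptide when its
#' start is a native N-terminus or a non-enzyme-specific (neo) start:
#' internal LysargiNase peptides that leak through isolation always
#' begin at a Lys/Arg, so a non-specific start identifies a proteoform
#' N-terminus. For CHAMP-NC an entry is terminal when it starts at a
#' native N-terminus or ends at the protein C-terminus; for CHAMP-C
#' when it ends at the protein C-terminus.
#'
#' @param evidence Evidence data frame (`accession`, `sequence`,
#'   `start`, `method`).
#' @param proteome A `champ_proteome`.
#' @param imet_rule Residues permitting iMet removal.
#' @return Logical vector aligned with `evidence` rows.
#' @export
is_terminal_entry <- function(evidence, proteome,
                              imet_rule = IMET_REMOVABLE) {
  vapply(seq_len(nrow(evidence)), function(i) {
    s <- protein_sequence(proteome, evidence$accession[i])
    st <- evidence$start[i]
    en <- st + nchar(evidence$sequence[i]) - 1L
    nt <- is_native_start(st, s, imet_rule)
    ct <- en == nchar(s)
    neo_start <- !substr(s, st, st) %in% c("K", "R")
    switch(evidence$method[i],
           CHAMP_N = nt || neo_start,
           CHAMP_C = ct,
           CHAMP_NC = nt || ct,
           stop("unknown method: ", evidence$method[i]))
  }, logical(1))
}

#' Z-value distribution of identified peptides
#'
#' @param Z Integer vector of per-peptide charge numbers (e.g. from
#'   [select_peptides()] output).
#' @param fraction Optional grouping vector (fraction id) for the
#'   per-fraction variant.
#' @return A named count table `Z -> count`, or a `fraction x Z` table
#'   when `fraction` is given.
#' @export
z_distribution <- function(Z, fraction = NULL) {
  if (!length(Z)) return(table(integer()))
  if (is.null(fraction)) table(Z) else table(fraction, Z)
}

#' Replicate reproducibility as per-peptide RSD
#'
#' For each peptide observed in at least two replicates, the relative
#' standard deviation (%) of its per-replicate intensities:
#' `100 * sd / mean`, where each replicate's intensity is the mean over
#' its injections (here: the sum of that replicate's entries for the
#' peptide, since injections are not modeled separately).
#'
#' @param evidence Evidence data frame with `accession`, `sequence`,
#'   `start`, `replicate`, `intensity`.
#' @return Data frame with `peptide_id`, `n_replicates`, `mean`, `rsd`
#'   (one row per peptide with >= 2 replicates and usable intensities).
#' @export
replicate_rsd <- function(evidence) {
  out <- data.frame(peptide_id = character(), n_replicates = integer(),
                    mean = numeric(), rsd = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(evidence) == 0L) return(out)
  id <- paste(evidence$accession, evidence$start, evidence$sequence,
              evidence$nt_mod, sep = "|")
  for (pid in unique(id)) {
    rows <- evidence[id == pid & !is.na(evidence$intensity), , drop = FALSE]
    if (nrow(rows) == 0L) next
    per_rep <- tapply(rows$intensity, rows$replicate, sum)
    if (length(per_rep) < 2L) next
    m <- mean(per_rep)
    out <- rbind(out, data.frame(
      peptide_id = pid, n_replicates = length(per_rep), mean = m,
      rsd = 100 * stats::sd(per_rep) / m, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Overlap of protein sets identified by the three methods
#'
#' Partitions the union of the three per-method protein(-group) sets
#' into the seven exclusive regions of the three-set Venn diagram.
#' Protein groups are approximated by accession.
#'
#' @param sets Named list of three character vectors (method id ->
#'   accessions).
#' @return List with `regions` (named counts, names like
#'   `"CHAMP_N"`, `"CHAMP_N&CHAMP_NC"`, ...), `union` (total distinct)
#'   and `per_method` counts.
#' @export
method_overlap <- function(sets) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                                  dimnames = list(NULL, names(sets)))
  region_of <- apply(membership, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  regions <- integer(0)
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)))
  for (cb in combos) regions[cb] <- sum(region_of == cb)
  list(regions = regions,
       union = length(all_ids),
       per_method = vapply(sets, length, integer(1)))
}

#' Per-fraction identification overlap and cumulative capture
#'
#' For an ordered series of elution fractions, reports how many
#' peptides each fraction contributes and what share of all identified
#' peptides is captured by pooling fractions 1..k — the quantity that
#' tells you how few fractions you can collect without losing
#' N-terminal peptides.
#'
#' @param fractions Ordered list of character vectors (peptide ids per
#'   fraction).
#' @return Data frame with `fraction`, `n`, `n_new`, `cumulative_n`,
#'   `cumulative_fraction`.
#' @export
fraction_overlap <- function(fractions) {
  stopifnot(is.list(fractions), length(fractions) >= 1L)
  fractions <- lapply(fractions, unique)
  total <- length(unique(unlist(fractions)))
  seen <- character()
  out <- data.frame(fraction = seq_along(fractions),
                    n = vapply(fractions, length, integer(1)),
                    n_new = integer(length(fractions)),
                    cumulative_n = integer(length(fractions)),
                    cumulative_fraction = numeric(length(fractions)))
  for (k in seq_along(fractions)) {
    new <- setdiff(fractions[[k]], seen)
    seen <- union(seen, fractions[[k]])
    out$n_new[k] <- length(new)
    out$cumulative_n[k] <- length(seen)
    out$cumulative_fraction[k] <- length(seen) / total
  }
  out
}

#' Aggregate per-method report
#'
#' Computes, from a validated evidence table, the per-method summary a
#' terminome experiment is judged by: identified terminal peptides,
#' intensity-based selectivity, the Z distribution, per-peptide
#' replicate RSDs, and the cross-method protein overlap.
#'
#' @param evidence Evidence data frame (any mix of methods).
#' @param proteome A `champ_proteome`.
#' @param imet_rule Residues permitting iMet removal.
#' @return Object of class `champ_report`: a list with one entry per
#'   method (`n_entries`, `n_terminal_ids`, `selectivity_pct`,
#'   `z_histogram`, `rsd` data frame) plus `overlap`.
#' @export
champ_report <- function(evidence, proteome, imet_rule = IMET_REMOVABLE) {
  stopifnot(inherits(proteome, "champ_proteome"))
  terminal <- is_terminal_entry(evidence, proteome, imet_rule)
  methods <- sort(unique(evidence$method))
  per <- list()
  term_sets <- list()
  for (m in methods) {
    idx <- evidence$method == m
    ev <- evidence[idx, , drop = FALSE]
    zz <- vapply(seq_len(nrow(ev)), function(i)
      charge_z(ev$sequence[i], ev$nt_mod[i])$Z, integer(1))
    pep_id <- paste(ev$accession, ev$start, ev$sequence, sep = "|")
    per[[m]] <- list(
      n_entries = nrow(ev),
      n_terminal_ids = length(unique(pep_id[terminal[idx]])),
      selectivity_pct = selectivity(ev$intensity, terminal[idx]),
      z_histogram = z_distribution(zz),
      rsd = replicate_rsd(ev))
    term_sets[[m]] <- unique(ev$accession[terminal[idx]])
  }
  structure(c(per, list(overlap = if (length(term_sets) > 1L)
    method_overlap(term_sets) else NULL)),
    class = "champ_report")
}

#' @export
print.champ_report <- function(x, ...) {
  cat("champ_report\n")
  for (m in setdiff(names(x), "overlap")) {
    r <- x[[m]]
    cat(sprintf("  %s: %d entries, %d terminal peptides, selectivity %.1f%%\n",
                m, r$n_entries, r$n_terminal_ids, r$selectivity_pct))
  }
  if (!is.null(x$overlap))
    cat("  union of terminal proteins across methods:", x$overlap$union,
        "\n")
  invisible(x)
}

#' @export
summary.champ_report <- function(object, ...) {
  for (m in setdiff(names(object), "overlap")) {
    r <- object[[m]]
    cat("==", m, "==\n")
    cat(sprintf("entries %d | terminal ids %d | selectivity %.1f%%\n",
                r$n_entries, r$n_terminal_ids, r$selectivity_pct))
    cat("Z distribution:\n"); print(r$z_histogram)
    if (nrow(r$rsd))
      cat(sprintf("median replicate RSD %.1f%% over %d peptides\n",
                  stats::median(r$rsd$rsd), nrow(r$rsd)))
  }
  if (!is.null(object$overlap)) {
    cat("== overlap ==\n"); print(object$overlap$regions)
  }
  invisible(object)
}

#' @export
plot.champ_report <- function(x, ...) {
  methods <- setdiff(names(x), "overlap")
  old <- graphics::par(mfrow = c(1, length(methods)))
  on.exit(graphics::par(old))
  for (m in methods)
    graphics::barplot(x[[m]]$z_histogram, main = m, xlab = "Z",
                      ylab = "peptides", ...)
  invisible(x)
}
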