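#' Protease specificities
#'
#' Supported enzymes and the side of the target residue they cleave:
#' LysargiNase cleaves the N-terminal side of Lys/Arg (the mirror of
#' trypsin), trypsin the C-terminal side of Lys/Arg, and V8 protease
#' (Glu-C, bicarbonate conditions) the C-terminal side of Asp/Glu.
#'
#' @param name One of `"lysarginase"`, `"trypsin"`, `"v8"`.
#' @return A list with `name`, `residues` (target set) and `side`
#'   (`"n_terminal"` or `"c_terminal"`).
#' @export
enzyme_spec <- function(name = c("lysarginase", "trypsin", "v8")) {
  name <- match.arg(name)
  switch(name,
    lysarginase = list(name = name, residues = c("K", "R"),
                       side = "n_terminal"),
    trypsin     = list(name = name, residues = c("K", "R"),
                       side = "c_terminal"),
    v8          = list(name = name, residues = c("D", "E"),
                       side = "c_terminal"))
}

as_enzyme <- function(enzyme) {
  if (is.character(enzyme)) enzyme_spec(enzyme) else enzyme
}

#' Enzymatic cleavage boundaries of a protein sequence
#'
#' A boundary `i` lies between residues `i` and `i + 1`
#' (`1 <= i < length`). For an N-terminal-side enzyme there is a
#' boundary before every target residue not at position 1; for a
#' C-terminal-side enzyme, after every target residue not at the last
#' position. Proline blocking (no cleavage when the residue following
#' the site is Pro) is off by default: none of the supported specificity
#' rules here assume it.
#'
#' @param sequence Amino-acid string.
#' @param enzyme Enzyme name or [enzyme_spec()] list.
#' @param proline_blocks If `TRUE`, suppress boundaries followed by Pro.
#' @return Sorted integer vector of between-residue boundaries (possibly
#'   empty).
#' @examples
#' cleavage_sites("MKRAGDE", "lysarginase")  # 1 2
#' cleavage_sites("MKDAGEQ", "v8")           # 3 6
#' @export
cleavage_sites <- function(sequence, enzyme, proline_blocks = FALSE) {
  stopifnot(is.character(sequence), nchar(sequence) > 0L)
  enzyme <- as_enzyme(enzyme)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  hits <- which(res %in% enzyme$residues)
  b <- if (enzyme$side == "n_terminal") hits - 1L else hits
  b <- b[b >= 1L & b < n]
  if (proline_blocks) b <- b[res[b + 1L] != "P"]
  sort(unique(b))
}

#' Fully specific in-silico digest with missed cleavages
#'
#' Enumerates every peptide bounded by the protein termini or enzyme
#' cleavage boundaries that spans at most `max_missed` internal
#' boundaries. The zero-missed peptides tile the protein exactly.
#'
#' @param sequence Amino-acid string of the protein.
#' @param enzyme Enzyme name or [enzyme_spec()] list.
#' @param max_missed Maximum number of missed cleavage sites (default 2,
#'   the usual search setting for these enzymes).
#' @param accession Optional accession recorded in the output.
#' @param imet_rule Residues after which the initiator Met is considered
#'   removable, used for terminal-category labeling.
#' @param proline_blocks Passed to [cleavage_sites()].
#' @return Data frame with columns `accession`, `start`, `end`,
#'   `sequence`, `missed_cleavages`, `category`.
#' @examples
#' digest("MKRAGDE", "lysarginase", max_missed = 0)$sequence
#' @export
digest <- function(sequence, enzyme, max_missed = 2L, accession = NA_character_,
                   imet_rule = IMET_REMOVABLE, proline_blocks = FALSE) {
  stopifnot(max_missed >= 0L)
  enzyme <- as_enzyme(enzyme)
  n <- nchar(sequence)
  b <- c(0L, cleavage_sites(sequence, enzyme, proline_blocks), n)
  k <- length(b)
  starts <- integer(); ends <- integer(); missed <- integer()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m <- j - i - 1L
      if (m > max_missed) break
      starts <- c(starts, b[i] + 1L)
      ends <- c(ends, b[j])
      missed <- c(missed, m)
    }
  }
  peptide_frame(sequence, enzyme, starts, ends, missed, accession, imet_rule)
}

peptide_frame <- function(sequence, enzyme, starts, ends, missed,
                          accession, imet_rule) {
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; missed <- missed[ord]
  data.frame(
    accession = rep(accession, length(starts)),
    start = starts, end = ends,
    sequence = substring(sequence, starts, ends),
    missed_cleavages = missed,
    category = vapply(seq_along(starts), function(i)
      label_category(starts[i], ends[i], sequence, enzyme, imet_rule),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Default residue set permitting initiator-Met removal
#'
#' Methionine aminopeptidase excises the initiator Met when the second
#' residue has a small side chain; this is the conventional small-radius
#' set.
#' @export
IMET_REMOVABLE <- c("A", "C", "G", "P", "S", "T", "V")

#' Terminal category of a peptide within its protein
#'
#' `protein_nt` when the peptide starts at residue 1, or at residue 2 of
#' a Met-initiated protein whose second residue permits iMet removal;
#' `protein_ct` when it ends at the protein's last residue (a
#' whole-protein peptide is labeled `protein_nt`); otherwise `internal`
#' when the start is enzyme-specific and `neo_nt` when it is not.
#'
#' @param start,end 1-based peptide coordinates.
#' @param sequence Protein amino-acid string.
#' @param enzyme Enzyme name or [enzyme_spec()] list.
#' @param imet_rule Residues permitting iMet removal.
#' @return One of `"protein_nt"`, `"protein_ct"`, `"internal"`,
#'   `"neo_nt"`.
#' @export
label_category <- function(start, end, sequence, enzyme,
                           imet_rule = IMET_REMOVABLE) {
  n <- nchar(sequence)
  stopifnot(start >= 1L, end >= start, end <= n)
  if (is_native_start(start, sequence, imet_rule)) return("protein_nt")
  if (end == n) return("protein_ct")
  enzyme <- as_enzyme(enzyme)
  specific <- if (enzyme$side == "n_terminal")
    substr(sequence, start, start) %in% enzyme$residues
  else
    start > 1L && substr(sequence, start - 1L, start - 1L) %in% enzyme$residues
  if (specific) "internal" else "neo_nt"
}

is_native_start <- function(start, sequence, imet_rule = IMET_REMOVABLE) {
  start == 1L ||
    (start == 2L && substr(sequence, 1L, 1L) == "M" &&
       substr(sequence, 2L, 2L) %in% imet_rule)
}

#' Semi-specific digest with a free N-terminus
#'
#' Emulates an "N-terminal free" semi-specific search space: the
#' C-terminal end of each peptide must be an enzyme boundary or the
#' protein C-terminus, but the start may be any residue. Used to
#' enumerate candidate neo-N-terminal peptides. Missed cleavages are
#' counted as internal boundaries spanned, and starts that do not
#' coincide with a specific boundary are labeled `neo_nt` (unless they
#' are a native start or protein C-terminal peptide).
#'
#' @inheritParams digest
#' @param min_len,max_len Peptide length bounds (defaults 6 and 45).
#' @return Data frame as for [digest()], restricted to the length
#'   bounds.
#' @export
semi_specific_nt_free <- function(sequence, enzyme, max_missed = 2L,
                                  min_len = 6L, max_len = 45L,
                                  accession = NA_character_,
                                  imet_rule = IMET_REMOVABLE,
                                  proline_blocks = FALSE) {
  stopifnot(min_len >= 1L, min_len <= max_len, max_missed >= 0L)
  enzyme <- as_enzyme(enzyme)
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, enzyme, proline_blocks)
  ends_ok <- c(sites, n)
  starts <- integer(); ends <- integer(); missed <- integer()
  for (e in ends_ok) {
    smin <- max(1L, e - max_len + 1L)
    smax <- e - min_len + 1L
    if (smax < smin) next
    for (s in smin:smax) {
      m <- sum(sites > s - 1L & sites < e)
      if (m > max_missed) next
      starts <- c(starts, s); ends <- c(ends, e); missed <- c(missed, m)
    }
  }
  peptide_frame(sequence, enzyme, starts, ends, missed, accession, imet_rule)
}

#' Digest every protein of a loaded proteome
#'
#' @param proteome A `champ_proteome`.
#' @inheritParams digest
#' @param semi_nt_free If `TRUE` use [semi_specific_nt_free()].
#' @param min_len,max_len Length bounds for the semi-specific digest.
#' @return Row-bound peptide data frame across all proteins.
#' @export
digest_proteome <- function(proteome, enzyme, max_missed = 2L,
                            semi_nt_free = FALSE, min_len = 6L,
                            max_len = 45L, imet_rule = IMET_REMOVABLE) {
  stopifnot(inherits(proteome, "champ_proteome"))
  out <- lapply(names(proteome$sequences), function(acc) {
    s <- proteome$sequences[[acc]]
    if (semi_nt_free)
      semi_specific_nt_free(s, enzyme, max_missed, min_len, max_len,
                            accession = acc, imet_rule = imet_rule)
    else
      digest(s, enzyme, max_missed, accession = acc, imet_rule = imet_rule)
  })
  do.call(rbind, out)
}
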