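#' Read a proteome FASTA with optional terminal-feature annotations
#'
#' Loads protein sequences and joins UniProt-style terminal features
#' (signal/transit peptide spans, initiator-Met removal, Nt-acetylation)
#' by accession. The accession is the first whitespace-separated token of
#' each FASTA header.
#'
#' @param fasta_path Path to a proteome FASTA file.
#' @param feature_tsv_path Optional path to a feature TSV with columns
#'   `accession`, `kind` (one of `signal_peptide`, `transit_peptide`,
#'   `imet_removed`, `nt_acetyl`), `start`, `end` and optionally
#'   `evidence` (`experimental`, `predicted`, `unknown`).
#' @return A `champ_proteome`: a list with `sequences` (named character
#'   vector of amino-acid sequences) and `features` (data frame).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MASTKLLRE"), fa)
#' prot <- read_proteome(fa)
#' protein_length(prot, "P1")
#' @export
read_proteome <- function(fasta_path, feature_tsv_path = NULL) {
  stopifnot(file.exists(fasta_path))
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) == 0L) stop("no sequences in FASTA: ", fasta_path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicated accessions in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- acc
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop("non-canonical residues in: ", paste(acc[bad], collapse = ", "))

  features <- empty_features()
  if (!is.null(feature_tsv_path)) {
    stopifnot(file.exists(feature_tsv_path))
    features <- utils::read.delim(feature_tsv_path, stringsAsFactors = FALSE)
    features <- validate_features(features, seqs)
  }
  structure(list(sequences = seqs, features = features),
            class = "champ_proteome")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

FEATURE_KINDS <- c("signal_peptide", "transit_peptide", "imet_removed",
                   "nt_acetyl")

empty_features <- function() {
  data.frame(accession = character(), kind = character(),
             start = integer(), end = integer(), evidence = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, seqs) {
  if (nrow(features) == 0L) return(empty_features())
  need <- c("accession", "kind", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(features$evidence)) features$evidence <- "unknown"
  bad_kind <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad_kind)) stop("unknown feature kind: ",
                             paste(bad_kind, collapse = ", "))
  unmatched <- setdiff(features$accession, names(seqs))
  if (length(unmatched)) {
    warning("feature rows for accessions absent from the proteome dropped: ",
            paste(unmatched, collapse = ", "))
    features <- features[features$accession %in% names(seqs), , drop = FALSE]
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    len <- nchar(seqs[[f$accession]])
    if (is.na(f$start) || is.na(f$end) || f$start < 1L || f$start > f$end ||
        f$end > len)
      stop("feature span [", f$start, ",", f$end, "] outside 1..", len,
           " for ", f$accession)
    if (f$kind %in% c("signal_peptide", "transit_peptide") && f$start != 1L)
      stop(f$kind, " must start at residue 1 (", f$accession, ")")
  }
  for (k in c("signal_peptide", "transit_peptide")) {
    tab <- table(features$accession[features$kind == k])
    if (any(tab > 1L))
      stop("more than one ", k, " for ",
           paste(names(tab)[tab > 1L], collapse = ", "))
  }
  sig <- unique(features$accession[features$kind == "signal_peptide"])
  tra <- unique(features$accession[features$kind == "transit_peptide"])
  both <- intersect(sig, tra)
  if (length(both))
    warning("accessions with both signal and transit peptide: ",
            paste(both, collapse = ", "))
  rownames(features) <- NULL
  features
}

#' @export
print.champ_proteome <- function(x, ...) {
  cat("champ_proteome:", length(x$sequences), "proteins,",
      nrow(x$features), "features\n")
  lens <- nchar(x$sequences)
  cat("  length range:", min(lens), "-", max(lens), "residues\n")
  if (nrow(x$features))
    print(table(x$features$kind))
  invisible(x)
}

#' Sequence and length accessors for a loaded proteome
#' @param proteome A `champ_proteome`.
#' @param accession Protein accession.
#' @return `protein_sequence()` the amino-acid string;
#'   `protein_length()` its length.
#' @export
protein_sequence <- function(proteome, accession) {
  s <- proteome$sequences[[accession]]
  if (is.null(s)) stop("unknown accession: ", accession)
  s
}

#' @rdname protein_sequence
#' @export
protein_length <- function(proteome, accession)
  nchar(protein_sequence(proteome, accession))

#' Parse a presequence span written as "start-end" or a bare end position
#'
#' Tolerates hyphen and en-dash separators ("1-24", "1–24"), bare
#' integers ("24"), and returns `NA` for unknown spans ("-", "?", "1-?").
#'
#' @param x Character vector of spans.
#' @return Integer vector of presequence end positions (the mature chain
#'   starts at end + 1).
#' @export
parse_span_end <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    s <- gsub("–", "-", x[i])
    if (is.na(s) || s %in% c("", "-", "?", "NA")) next
    if (grepl("-", s, fixed = TRUE))
      s <- utils::tail(strsplit(s, "-", fixed = TRUE)[[1]], 1L)
    s <- trimws(s)
    if (grepl("^[0-9]+$", s)) out[i] <- as.integer(s)
  }
  out
}

#' Read predicted presequence cleavage ends
#'
#' Reads predictor output (signal- or transit-peptide prediction) into a
#' table of cleavage ends: the mature protein starts at
#' `presequence_end + 1`.
#'
#' @param tsv_path TSV with columns `accession` and `presequence_end`
#'   (span string "1-N" or bare integer N).
#' @param predictor `"signal_predictor"` or `"transit_predictor"`.
#' @return Data frame with columns `accession`, `predictor`,
#'   `presequence_end`.
#' @export
read_predictions <- function(tsv_path,
                             predictor = c("signal_predictor",
                                           "transit_predictor")) {
  predictor <- match.arg(predictor)
  stopifnot(file.exists(tsv_path))
  d <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("accession", "presequence_end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("prediction table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(d) == 0L)
    return(data.frame(accession = character(), predictor = character(),
                      presequence_end = integer(),
                      stringsAsFactors = FALSE))
  end <- parse_span_end(d$presequence_end)
  if (any(!is.na(end) & end < 1L))
    stop("non-positive presequence end for ",
         paste(d$accession[!is.na(end) & end < 1L], collapse = ", "))
  bad <- is.na(end) & !trimws(as.character(d$presequence_end)) %in%
    c("", "-", "?", "NA")
  if (any(bad))
    stop("unparseable presequence end for ",
         paste(d$accession[bad], collapse = ", "))
  data.frame(accession = d$accession, predictor = predictor,
             presequence_end = end, stringsAsFactors = FALSE)
}

#' Read an identified-peptide evidence table
#'
#' The evidence table is a simplified search-output schema: one row per
#' identified peptide per replicate, with columns `accession`,
#' `sequence`, `start` (1-based position of the peptide's first residue
#' in the protein), `nt_mod` (`free`/`acetyl`), `intensity` (may be
#' empty), `replicate` and `method` (`CHAMP_N`, `CHAMP_NC`, `CHAMP_C`).
#' Each row is validated against the loaded proteome: the protein
#' subsequence at `[start, start + nchar(sequence) - 1]` must equal
#' `sequence`.
#'
#' @param tsv_path Path to the evidence TSV.
#' @param proteome A `champ_proteome` to validate against.
#' @return Data frame of validated evidence entries.
#' @export
read_evidence <- function(tsv_path, proteome) {
  stopifnot(file.exists(tsv_path), inherits(proteome, "champ_proteome"))
  d <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    return(data.frame(accession = character(), sequence = character(),
                      start = integer(), nt_mod = character(),
                      intensity = numeric(), replicate = integer(),
                      method = character(), stringsAsFactors = FALSE))
  need <- c("accession", "sequence", "start", "nt_mod", "replicate",
            "method")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("evidence table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(d$intensity)) d$intensity <- NA_real_
  d$start <- as.integer(d$start)
  d$replicate <- as.integer(d$replicate)
  d$intensity <- suppressWarnings(as.numeric(d$intensity))
  validate_evidence(d, proteome)
}

validate_evidence <- function(d, proteome) {
  bad_method <- setdiff(unique(d$method),
                        c("CHAMP_N", "CHAMP_NC", "CHAMP_C"))
  if (length(bad_method)) stop("unknown method label: ",
                               paste(bad_method, collapse = ", "))
  bad_mod <- setdiff(unique(d$nt_mod), c("free", "acetyl"))
  if (length(bad_mod)) stop("unknown nt_mod: ",
                            paste(bad_mod, collapse = ", "))
  if (any(!is.na(d$intensity) & d$intensity < 0))
    stop("negative intensity in rows ",
         paste(which(!is.na(d$intensity) & d$intensity < 0), collapse = ", "))
  bad_rows <- integer()
  for (i in seq_len(nrow(d))) {
    prot <- proteome$sequences[[d$accession[i]]]
    if (is.null(prot)) { bad_rows <- c(bad_rows, i); next }
    s <- d$start[i]; e <- s + nchar(d$sequence[i]) - 1L
    if (is.na(s) || s < 1L || e > nchar(prot) ||
        substr(prot, s, e) != d$sequence[i])
      bad_rows <- c(bad_rows, i)
  }
  if (length(bad_rows))
    stop("evidence rows not matching the proteome subsequence: rows ",
         paste(bad_rows, collapse = ", "))
  rownames(d) <- NULL
  d
}

#' Write tabular pipeline outputs
#'
#' `write_tsv()` writes any of the pipeline's data frames (features,
#' evidence, decisions, calls) as a TSV that `read.delim()` round-trips.
#' `write_report()` writes an aggregate report both as JSON and, for its
#' tabular members, as TSV files alongside it.
#'
#' @param x Data frame to write.
#' @param path Output path (`write_report()` uses `path` for the JSON and
#'   derives `<path-sans-ext>_<member>.tsv` names for tables).
#' @param report A `champ_report` or plain named list.
#' @return The output path(s), invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  stem <- sub("\\.json$", "", path)
  written <- path
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      p <- paste0(stem, "_", nm, ".tsv")
      write_tsv(report[[nm]], p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Bundled worked examples of presequence cleavage-site matching
#'
#' Two curated tables of human proteins for which the observed
#' neo-N-terminal position is compared against a predicted signal- or
#' transit-peptide end and the UniProt-annotated span: columns
#' `accession`, `gene`, `predicted_span`, `neo_position`,
#' `uniprot_experimental`, `uniprot_span`, `topfind`. UniProt spans
#' lacking a defined end are stored as `"-"` or `"1-?"` and parse to
#' `NA` via [parse_span_end()].
#'
#' @param kind `"signal"` or `"transit"`.
#' @return Data frame with parsed integer columns `predicted_end` and
#'   `uniprot_end` appended.
#' @export
champ_cleavage_examples <- function(kind = c("signal", "transit")) {
  kind <- match.arg(kind)
  path <- system.file("extdata",
                      paste0(kind, "_cleavage_examples.tsv"),
                      package = "champtools", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$predicted_end <- parse_span_end(d$predicted_span)
  d$uniprot_end <- parse_span_end(d$uniprot_span)
  d
}
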