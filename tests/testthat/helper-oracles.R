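# Independent brute-force oracles and fixture builders used across the
# suite. The digestion oracle enumerates every substring and applies the
# boundary definitions directly, independent of digest()'s window
# construction.

oracle_sites <- function(sequence, enzyme) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (enzyme == "lysarginase") {
    b <- which(res %in% c("K", "R")) - 1L
  } else {
    targets <- if (enzyme == "v8") c("D", "E") else c("K", "R")
    b <- which(res %in% targets)
  }
  b[b >= 1L & b < n]
}

oracle_digest <- function(sequence, enzyme, max_missed) {
  n <- nchar(sequence)
  sites <- oracle_sites(sequence, enzyme)
  starts_ok <- c(1L, sites + 1L)
  ends_ok <- c(sites, n)
  out <- list()
  for (s in starts_ok) {
    for (e in ends_ok) {
      if (e < s) next
      m <- sum(sites > s - 1L & sites < e)
      if (m <= max_missed)
        out[[length(out) + 1L]] <- c(s, e, m)
    }
  }
  d <- as.data.frame(do.call(rbind, out))
  names(d) <- c("start", "end", "missed_cleavages")
  d[order(d$start, d$end), , drop = FALSE]
}

oracle_semi_count <- function(sequence, enzyme, max_missed, min_len,
                              max_len) {
  n <- nchar(sequence)
  sites <- oracle_sites(sequence, enzyme)
  ends_ok <- c(sites, n)
  count <- 0L
  for (s in seq_len(n)) {
    for (e in ends_ok) {
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      if (sum(sites > s - 1L & sites < e) <= max_missed)
        count <- count + 1L
    }
  }
  count
}

# maximal runs of consecutive integers, scanned directly
oracle_runs <- function(positions, min_run) {
  p <- sort(unique(positions))
  if (!length(p)) return(list())
  runs <- list()
  s <- p[1]; prev <- p[1]
  for (x in p[-1]) {
    if (x != prev + 1L) {
      if (prev - s + 1L >= min_run) runs[[length(runs) + 1L]] <- c(s, prev)
      s <- x
    }
    prev <- x
  }
  if (prev - s + 1L >= min_run) runs[[length(runs) + 1L]] <- c(s, prev)
  runs
}

random_protein <- function(len, aa = c("A", "C", "D", "E", "F", "G", "H",
                                       "I", "K", "L", "M", "N", "P", "Q",
                                       "R", "S", "T", "V", "W", "Y")) {
  paste0("M", paste(sample(aa, len - 1L, replace = TRUE), collapse = ""))
}

make_proteome <- function(sequences, features = NULL) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(sequences), function(a)
    c(paste0(">", a), sequences[[a]]))), fa)
  ft <- NULL
  if (!is.null(features)) {
    ft <- tempfile(fileext = ".tsv")
    utils::write.table(features, ft, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  read_proteome(fa, ft)
}
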