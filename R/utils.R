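# Small shared helpers: alphabet handling, reverse complements, UMIs.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a sequence to the RNA alphabet
#'
#' Uppercases and replaces T with U. Used to normalize snoRNA and target
#' sequences before motif search and duplex scoring, so DNA and RNA input
#' are interchangeable.
#'
#' @param x character vector of sequences.
#' @return character vector in A/C/G/U(/N).
#' @export
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement of an RNA/DNA sequence
#'
#' Operates on plain character vectors; T is treated as U and the result
#' is returned in the RNA alphabet. N maps to N.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
revcomp_rna <- function(x) {
  x <- to_rna(x)
  vapply(x, function(s) {
    s <- chartr("ACGUN", "UGCAN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse complement staying in the DNA alphabet (genomic windows).
revcomp_dna <- function(x) {
  vapply(toupper(x), function(s) {
    s <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# n uniformly random UMIs of the given length (A/C/G/T).
random_umis <- function(n, umi_length) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * umi_length, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Deterministic small sub-seed derivation (kept well below .Machine$integer.max).
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Standard column set for aligned 3'-end records.
empty_records <- function() {
  data.frame(contig = character(0), strand = character(0),
             end3 = integer(0), umi = character(0),
             read_length = integer(0), mean_quality = numeric(0),
             stringsAsFactors = FALSE)
}

# Standard column set for called Nm sites.
empty_sites <- function(sample = NA_character_) {
  data.frame(contig = character(0), pos = integer(0), strand = character(0),
             dedup_count = integer(0), nm_score = numeric(0),
             sample = character(0), stringsAsFactors = FALSE)
}
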