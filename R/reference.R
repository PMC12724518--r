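#' Build a synthetic reference with transcript annotation
#'
#' Generates random contig sequences and places non-overlapping
#' single-exon transcript models on them, each split into 5'UTR, CDS and
#' 3'UTR segments according to `proportions`. The reference stands in for
#' a genome assembly at desk scale; contigs are i.i.d. uniform ACGT.
#'
#' Coordinates are 0-based, half-open throughout the package (BED
#' convention).
#'
#' @param contig_lengths named integer vector of contig lengths (>= 1000 nt).
#' @param n_transcripts transcripts per contig.
#' @param proportions length-3 numeric, fractions of each transcript given
#'   to 5'UTR, CDS and 3'UTR; must sum to 1.
#' @param coverage fraction of each contig covered by transcripts
#'   (transcripts are equally sized, evenly spaced, alternating strand).
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @return an object of class `nm_reference`: list with `contigs`
#'   (named [Biostrings::DNAStringSet]) and `transcripts` (data.frame with
#'   columns transcript_id, contig, strand, start, end, cds_start, cds_end;
#'   0-based half-open).
#' @export
build_reference <- function(contig_lengths = c(chr1 = 10000L),
                            n_transcripts = 5L,
                            proportions = c(0.05, 0.55, 0.40),
                            coverage = 0.7,
                            seed = 1L) {
  stop_if_not(all(contig_lengths >= 1000L), "contig lengths must be >= 1000 nt")
  stop_if_not(length(proportions) == 3 && all(proportions >= 0),
              "proportions must be three non-negative fractions")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1 (got ", sum(proportions), ")", call. = FALSE)
  stop_if_not(coverage > 0 && coverage <= 0.95, "coverage must be in (0, 0.95]")
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))

  withr::with_seed(seed, {
    contigs <- Biostrings::DNAStringSet(vapply(contig_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    tx <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
      L <- contig_lengths[[ctg]]
      slot <- L %/% n_transcripts
      tx_len <- as.integer(floor(slot * coverage))
      starts <- as.integer((seq_len(n_transcripts) - 1L) * slot +
                             (slot - tx_len) %/% 2L)
      seg <- segment_lengths(tx_len, proportions)
      strand <- rep(c("+", "-"), length.out = n_transcripts)
      # In transcript orientation the 5'UTR comes first; on the minus strand
      # that is the genomically rightmost segment.
      cds_start <- ifelse(strand == "+", starts + seg[1L],
                          starts + seg[3L])
      data.frame(transcript_id = sprintf("%s_tx%d", ctg, seq_len(n_transcripts)),
                 contig = ctg, strand = strand,
                 start = starts, end = starts + tx_len,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_start + seg[2L]),
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(contigs = contigs, transcripts = tx), class = "nm_reference")
}

# Split a transcript length into (5'UTR, CDS, 3'UTR) segment lengths whose
# sum is exact and each within 1 nt of length * proportion.
segment_lengths <- function(tx_len, proportions) {
  raw <- tx_len * proportions
  seg <- floor(raw)
  rem <- tx_len - sum(seg)
  if (rem > 0) {
    order_frac <- order(raw - seg, decreasing = TRUE)
    seg[order_frac[seq_len(rem)]] <- seg[order_frac[seq_len(rem)]] + 1
  }
  as.integer(seg)
}

#' @export
print.nm_reference <- function(x, ...) {
  cat("nm_reference:", length(x$contigs), "contig(s),",
      nrow(x$transcripts), "transcript model(s)\n")
  invisible(x)
}

# Total transcript nucleotides per contig/strand; used by the simulators.
transcript_positions <- function(reference) {
  tx <- reference$transcripts
  tx$width <- tx$end - tx$start
  tx
}

contig_length <- function(reference, contig) {
  stop_if_not(contig %in% names(reference$contigs),
              paste0("unknown contig: ", contig))
  length(reference$contigs[[contig]])
}

# Extract [start, end) of a contig as a character string (DNA alphabet).
contig_window <- function(reference, contig, start, end) {
  L <- contig_length(reference, contig)
  stop_if_not(start >= 0 && end <= L && end > start,
              paste0("window [", start, ",", end, ") outside contig ", contig))
  as.character(Biostrings::subseq(reference$contigs[[contig]],
                                  start + 1L, end))
}
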