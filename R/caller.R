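# From aligned 3'-end records to deduplicated coverage and called Nm sites.

#' Quality-filter aligned 3'-end records
#'
#' Keeps records whose read length and mean base quality both strictly
#' exceed the thresholds (length > 20 nt, quality > 20 by default).
#'
#' @param records data.frame of aligned 3'-end records.
#' @param min_length,min_quality strict lower thresholds (>= 0).
#' @return the filtered records.
#' @export
filter_records <- function(records, min_length = 20, min_quality = 20) {
  stop_if_not(min_length >= 0 && min_quality >= 0, "thresholds must be >= 0")
  keep <- records$read_length > min_length & records$mean_quality > min_quality
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse PCR duplicates by UMI
#'
#' Retains exactly one record per distinct (contig, strand, end3, umi)
#' key, keeping the first occurrence in input order. Exact-match
#' deduplication only; no mismatch-tolerant UMI network collapse.
#'
#' @param records data.frame of aligned 3'-end records carrying UMIs.
#' @return deduplicated records.
#' @export
dedupe_umis <- function(records) {
  if (nrow(records) == 0L) return(records)
  stop_if_not(all(grepl("^[ACGT]+$", records$umi)),
              "UMIs must be non-empty A/C/G/T strings")
  keep <- !duplicated(records[, c("contig", "strand", "end3", "umi")])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-nucleotide 3'-end coverage
#'
#' Counts deduplicated records per (contig, strand, position) and records
#' the library size (total deduplicated records).
#'
#' @param records deduplicated records (see [dedupe_umis()]).
#' @return object of class `end_coverage`: list with `counts` (data.frame
#'   contig, strand, pos, count, sorted) and `library_size`.
#' @export
end3_coverage <- function(records) {
  if (nrow(records) == 0L) {
    counts <- data.frame(contig = character(0), strand = character(0),
                         pos = integer(0), count = integer(0),
                         stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(records))),
                            by = list(contig = records$contig,
                                      strand = records$strand,
                                      pos = records$end3),
                            FUN = sum)
    counts <- agg[order(agg$contig, agg$strand, agg$pos), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, library_size = nrow(records)),
            class = "end_coverage")
}

#' @export
print.end_coverage <- function(x, ...) {
  cat("end_coverage:", nrow(x$counts), "position(s), library size",
      x$library_size, "\n")
  invisible(x)
}

#' Nm score of a position
#'
#' The deduplicated 3'-end count normalized to counts per 20 million
#' deduplicated library reads: `count * 2e7 / library_size`, reported to
#' one decimal. Positions absent from the coverage score 0 by convention.
#'
#' @param coverage an `end_coverage`.
#' @param contig,pos,strand position (0-based).
#' @return numeric score (>= 0).
#' @export
nm_score <- function(coverage, contig, pos, strand) {
  if (coverage$library_size == 0L)
    stop("library size is 0; Nm score undefined", call. = FALSE)
  cc <- coverage$counts
  i <- which(cc$contig == contig & cc$strand == strand & cc$pos == pos)
  count <- if (length(i) == 0L) 0L else cc$count[i[1L]]
  round(count * 2e7 / coverage$library_size, 1)
}

# Vectorized Nm scores for a table of positions (0 where absent).
score_positions <- function(coverage, positions) {
  if (nrow(positions) == 0L) return(numeric(0))
  if (coverage$library_size == 0L)
    stop("library size is 0; Nm score undefined", call. = FALSE)
  cc <- coverage$counts
  key <- paste(cc$contig, cc$strand, cc$pos)
  i <- match(paste(positions$contig, positions$strand, positions$pos), key)
  count <- ifelse(is.na(i), 0L, cc$count[i])
  round(count * 2e7 / coverage$library_size, 1)
}

#' Call Nm sites from 3'-end coverage
#'
#' A position is called when its Nm score reaches `score_threshold` and
#' its deduplicated count is at least `enrichment_fold` times the median
#' count over the +/- `flank` nt window around it (the position itself
#' excluded; positions without coverage count as 0; a median of 0 is
#' treated as 1 so the ratio is defined). The local-enrichment criterion
#' keeps plateau positions of highly expressed transcripts from being
#' called on score alone.
#'
#' @param coverage an `end_coverage`.
#' @param score_threshold minimum Nm score.
#' @param enrichment_fold minimum fold enrichment over the flank median.
#' @param flank half-width of the local window (nt, >= 1).
#' @param sample sample label recorded on the output.
#' @return data.frame of called sites sorted by (contig, pos): contig,
#'   pos, strand, dedup_count, nm_score, sample.
#' @export
call_sites <- function(coverage, score_threshold = 500,
                       enrichment_fold = 10, flank = 50L,
                       sample = NA_character_) {
  stop_if_not(flank >= 1L, "flank must be >= 1")
  cc <- coverage$counts
  if (nrow(cc) == 0L) return(empty_sites())
  scores <- round(cc$count * 2e7 / coverage$library_size, 1)
  cand <- which(scores >= score_threshold)
  called <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    same <- cc$contig == cc$contig[i] & cc$strand == cc$strand[i]
    win <- same & cc$pos >= cc$pos[i] - flank & cc$pos <= cc$pos[i] + flank &
      cc$pos != cc$pos[i]
    vals <- c(cc$count[win], rep(0L, 2L * flank - sum(win)))
    med <- stats::median(vals)
    if (med == 0) med <- 1
    called[k] <- cc$count[i] >= enrichment_fold * med
  }
  idx <- cand[called]
  if (length(idx) == 0L) return(empty_sites())
  out <- data.frame(contig = cc$contig[idx], pos = cc$pos[idx],
                    strand = cc$strand[idx], dedup_count = cc$count[idx],
                    nm_score = scores[idx], sample = sample,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the k highest-scoring sites
#'
#' Sites are ranked by Nm score; ties at the rank boundary are broken
#' deterministically by (contig, pos) lexicographic order.
#'
#' @param sites data.frame of called sites.
#' @param k number of sites to keep (>= 1).
#' @return the top k sites (all sites, with a warning, when k exceeds the
#'   number available).
#' @export
top_k <- function(sites, k = 500L) {
  stop_if_not(k >= 1L, "k must be >= 1")
  if (k > nrow(sites)) {
    warning("k = ", k, " exceeds the ", nrow(sites), " available sites")
    k <- nrow(sites)
  }
  ord <- order(-sites$nm_score, sites$contig, sites$pos)
  out <- sites[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
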