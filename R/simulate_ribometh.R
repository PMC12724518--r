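# Alkaline-fragmentation end-profile simulator (RiboMeth-seq-style).

#' Simulate per-nucleotide read-end profiles
#'
#' Alkaline hydrolysis requires the 2'-OH, so cleavage of the bond 3' of
#' position n is suppressed in proportion to that position's methylation
#' stoichiometry. Read 3'-end counts at n and 5'-end counts at n+1 are
#' drawn as independent Poisson variates with mean
#' `depth * (1 - effective fraction at n)` at truth sites and mean
#' `depth` elsewhere. Replicates use distinct deterministic sub-seeds.
#'
#' Profiles are generated for every (contig, strand) combination carrying
#' at least one transcript.
#'
#' @param reference an `nm_reference`.
#' @param truth an `nm_truth`.
#' @param depth expected cleavage reads per junction.
#' @param replicates number of replicate profiles.
#' @param condition condition label in `truth$conditions`.
#' @param seed integer seed.
#' @return list of `end_profile` objects, one per
#'   (contig, strand, replicate): list with contig, strand, replicate_id
#'   and dense integer vectors `ends5`, `ends3` indexed by 0-based
#'   position + 1.
#' @export
simulate_ribometh <- function(reference, truth, depth = 1000,
                              replicates = 3L, condition = "CT2",
                              seed = 1L) {
  stop_if_not(depth > 0, "depth must be > 0")
  stop_if_not(replicates >= 1L, "replicates must be >= 1")
  stop_if_not(condition %in% truth$conditions,
              paste0("unknown condition: ", condition))
  frac <- effective_fractions(truth, condition)
  sites <- truth$sites
  tx <- reference$transcripts

  combos <- unique(tx[, c("contig", "strand")])
  out <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_len(nrow(combos))) {
      ctg <- combos$contig[i]; strand <- combos$strand[i]
      L <- contig_length(reference, ctg)
      lambda <- rep(depth, L)  # cleavage intensity of junction 3' of pos n
      sel <- sites$contig == ctg & sites$strand == strand
      if (any(sel))
        lambda[sites$pos[sel] + 1L] <- depth * (1 - frac[sel])
      prof <- withr::with_seed(sub_seed(seed, (r - 1L) * 100L + i), {
        ends3 <- stats::rpois(L, lambda)
        # 5' ends sit one position 3' of the cleaved junction
        ends5 <- integer(L)
        if (L > 1L) ends5[2:L] <- stats::rpois(L - 1L, lambda[1:(L - 1L)])
        list(ends3 = ends3, ends5 = ends5)
      })
      out[[length(out) + 1L]] <- end_profile(ctg, strand, r,
                                             ends5 = prof$ends5,
                                             ends3 = prof$ends3)
    }
  }
  out
}

#' Construct an end profile
#'
#' Container for per-nucleotide counts of read 5' and 3' ends on one
#' contig and strand.
#'
#' @param contig,strand location.
#' @param replicate_id replicate label.
#' @param ends5,ends3 equal-length non-negative integer vectors; element
#'   i holds the count at 0-based position i - 1.
#' @return object of class `end_profile`.
#' @export
end_profile <- function(contig, strand, replicate_id, ends5, ends3) {
  stop_if_not(length(ends5) == length(ends3),
              "ends5 and ends3 must have equal length")
  stop_if_not(all(ends5 >= 0) && all(ends3 >= 0), "counts must be >= 0")
  structure(list(contig = contig, strand = strand,
                 replicate_id = replicate_id,
                 ends5 = as.integer(ends5), ends3 = as.integer(ends3)),
            class = "end_profile")
}

#' @export
print.end_profile <- function(x, ...) {
  cat("end_profile", x$contig, x$strand, "replicate", x$replicate_id,
      "-", length(x$ends3), "positions\n")
  invisible(x)
}
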