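# Generative model for oxidation-based 3'-end sequencing.

#' Simulation configuration
#'
#' Parameters of the 3'-end sequencing simulator.
#'
#' @param depth expected molecules per contig per sample.
#' @param background_end_rate per-molecule probability that an
#'   unprotected (fully trimmed, still unmethylated) terminus ligates
#'   anyway; must be below 0.01.
#' @param trim_budget maximum number of 3' nucleotides removable by the
#'   iterative oxidation / beta-elimination cycles (default 4: the
#'   protocol's four cycles, with the final blocking oxidation modelled
#'   as discarding unprotected termini).
#' @param umi_length unique molecular identifier length (nt).
#' @param replicates replicate libraries per condition.
#' @param read_length_range,quality_range uniform ranges for simulated
#'   read lengths and mean base qualities. Defaults lie entirely above
#'   the standard quality filter so that filtering does not thin
#'   simulated libraries.
#' @return list of class `nm_sim_config`.
#' @export
nm_sim_config <- function(depth = 100000, background_end_rate = 1e-4,
                          trim_budget = 4L, umi_length = 10L,
                          replicates = 1L,
                          read_length_range = c(30L, 150L),
                          quality_range = c(25, 40)) {
  stop_if_not(depth > 0, "depth must be > 0")
  stop_if_not(background_end_rate >= 0 && background_end_rate < 0.01,
              "background_end_rate must be in [0, 0.01)")
  stop_if_not(trim_budget >= 1L, "trim_budget must be >= 1")
  stop_if_not(umi_length >= 1L, "umi_length must be >= 1")
  stop_if_not(replicates >= 1L, "replicates must be >= 1")
  structure(list(depth = depth, background_end_rate = background_end_rate,
                 trim_budget = as.integer(trim_budget),
                 umi_length = as.integer(umi_length),
                 replicates = as.integer(replicates),
                 read_length_range = as.integer(read_length_range),
                 quality_range = quality_range),
            class = "nm_sim_config")
}

#' Simulate aligned 3'-end records for one condition
#'
#' Per-molecule generative model mirroring the oxidation/ligation
#' chemistry:
#'
#' 1. Fragmentation places a random 3' terminus uniformly over transcript
#'    positions. Cleavage immediately 3' of a 2'-O-methylated nucleotide
#'    is chemically blocked, so molecules whose sampled terminus is
#'    methylated (per that molecule's Bernoulli draw at the site's
#'    effective fraction) are rejected.
#' 2. Each truth site is methylated in a given molecule with probability
#'    equal to its effective stoichiometry in the condition.
#' 3. Oxidation trims the 3' terminus one unmethylated nucleotide at a
#'    time, up to `trim_budget` nucleotides; trimming stops at the first
#'    methylated nucleotide, which becomes the recorded 3' end.
#' 4. Molecules still unmethylated at the terminus after the budget are
#'    discarded, except with probability `background_end_rate` (spurious
#'    ligation records the fully trimmed terminus).
#' 5. Surviving records get a uniformly random UMI, a read length and a
#'    mean base quality.
#'
#' For tandem (closely spaced) sites this model reproduces the method's
#' masking behaviour: trimming from downstream always stops at the most
#' 3' modified position, so an upstream partner is observed only in the
#' fraction of molecules in which the downstream site happens to be
#' unmethylated.
#'
#' @param reference an `nm_reference`.
#' @param truth an `nm_truth`.
#' @param config an [nm_sim_config()].
#' @param condition condition label in `truth$conditions`.
#' @param seed integer seed; output is bit-reproducible for a fixed seed.
#' @return data.frame of aligned 3'-end records: contig, strand, end3
#'   (0-based), umi, read_length, mean_quality.
#' @export
simulate_riboxi <- function(reference, truth, config, condition, seed = 1L) {
  stop_if_not(inherits(config, "nm_sim_config"), "config must be nm_sim_config")
  stop_if_not(condition %in% truth$conditions,
              paste0("unknown condition: ", condition))
  frac <- effective_fractions(truth, condition)
  sites <- truth$sites
  site_key <- paste(sites$contig, sites$strand, sites$pos)
  tx <- transcript_positions(reference)
  b <- config$trim_budget

  withr::with_seed(seed, {
    recs <- lapply(names(reference$contigs), function(ctg) {
      txc <- tx[tx$contig == ctg, , drop = FALSE]
      if (nrow(txc) == 0L) return(NULL)
      n <- stats::rpois(1L, config$depth)
      if (n == 0L) return(NULL)
      ti <- sample.int(nrow(txc), n, replace = TRUE, prob = txc$width)
      T0 <- txc$start[ti] + as.integer(floor(stats::runif(n) * txc$width[ti]))
      strand <- txc$strand[ti]
      dir <- ifelse(strand == "+", -1L, 1L)
      Lc <- contig_length(reference, ctg)

      rec_pos <- rep(NA_integer_, n)
      state <- rep("open", n)  # open | recorded | rejected
      for (k in 0:b) {
        p <- T0 + k * dir
        idx <- match(paste(ctg, strand, p), site_key)
        hit <- state == "open" & !is.na(idx) & p >= 0L & p < Lc
        if (any(hit)) {
          meth <- hit & (stats::runif(n) < frac[ifelse(is.na(idx), 1L, idx)])
          if (k == 0L) {
            # cleavage 3' of a methylated nucleotide cannot occur
            state[meth] <- "rejected"
          } else {
            rec_pos[meth] <- p[meth]
            state[meth] <- "recorded"
          }
        }
      }
      open <- state == "open"
      bg <- open & (stats::runif(n) < config$background_end_rate)
      pbg <- T0 + b * dir
      bg <- bg & pbg >= 0L & pbg < Lc
      rec_pos[bg] <- pbg[bg]
      keep <- !is.na(rec_pos)
      if (!any(keep)) return(NULL)
      data.frame(contig = ctg, strand = strand[keep],
                 end3 = rec_pos[keep], stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) return(empty_records())
    m <- nrow(recs)
    recs$umi <- random_umis(m, config$umi_length)
    recs$read_length <- sample(config$read_length_range[1]:
                                 config$read_length_range[2],
                               m, replace = TRUE)
    recs$mean_quality <- round(stats::runif(m, config$quality_range[1],
                                            config$quality_range[2]), 1)
    rownames(recs) <- NULL
    recs
  })
}
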