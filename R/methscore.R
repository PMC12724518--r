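# MethScore: protection against alkaline cleavage, normalized to the
# flanking positions.

#' End sum at a position
#'
#' `S(n) = ends3(n) + ends5(n + 1)`: both read-end categories produced by
#' cleavage of the phosphodiester bond 3' of position n. Positions
#' outside the profile contribute 0.
#'
#' @param profile an `end_profile`.
#' @param n 0-based position(s); vectorized.
#' @return integer end sum(s).
#' @export
end_sum <- function(profile, n) {
  L <- length(profile$ends3)
  stop_if_not(all(n >= 0 & n < L), "position outside contig")
  e3 <- profile$ends3[n + 1L]
  e5 <- ifelse(n + 2L <= L, profile$ends5[n + 2L], 0L)
  as.integer(e3 + e5)
}

#' MethScore at a position
#'
#' The end sum at n is compared with the weighted mean end sum of the
#' `flank` positions on each side and subtracted from 1. Two denominator
#' conventions are provided:
#'
#' * `"literal"` (default): the end sum is divided by **half** the
#'   weighted mean flank end sum, i.e.
#'   `raw = 1 - S(n) / (0.5 * sum(w * S_f) / sum(w))`. Under uniform
#'   cleavage this yields -1, so scores are clamped to `[0, 1]` unless
#'   `clamp = FALSE`.
#' * `"mean"`: `raw = 1 - S(n) / (sum(w * S_f) / sum(w))`, which equals
#'   the protection fraction (and hence the methylation stoichiometry)
#'   under uniform cleavage.
#'
#' The two raw scores obey `raw_literal = 2 * raw_mean - 1` exactly.
#' When every flank end sum is 0 the score is undefined (NA), as it is
#' when the flank window extends past the contig.
#'
#' @param profile an `end_profile`.
#' @param n 0-based position(s); vectorized.
#' @param flank flanking half-width in nucleotides (>= 1; default 2).
#' @param weights optional numeric vector of length `2 * flank` (flank
#'   positions ordered n-flank, ..., n-1, n+1, ..., n+flank); default
#'   uniform.
#' @param denominator_mode `"literal"` or `"mean"`.
#' @param clamp clamp the result to `[0, 1]` (default TRUE).
#' @return numeric score(s), NA where undefined.
#' @export
methscore <- function(profile, n, flank = 2L, weights = NULL,
                      denominator_mode = c("literal", "mean"),
                      clamp = TRUE) {
  denominator_mode <- match.arg(denominator_mode)
  stop_if_not(flank >= 1L, "flank must be >= 1")
  if (is.null(weights)) weights <- rep(1, 2L * flank)
  stop_if_not(length(weights) == 2L * flank && all(weights >= 0) &&
                sum(weights) > 0, "need 2*flank non-negative weights")
  L <- length(profile$ends3)
  offs <- c(-(flank:1), 1:flank)
  vapply(n, function(p) {
    if (p - flank < 0L || p + flank > L - 1L) return(NA_real_)
    sf <- end_sum(profile, p + offs)
    denom <- sum(weights * sf) / sum(weights)
    if (denom == 0) return(NA_real_)
    if (denominator_mode == "literal") denom <- 0.5 * denom
    raw <- 1 - end_sum(profile, p) / denom
    if (clamp) min(max(raw, 0), 1) else raw
  }, numeric(1))
}

#' MethScore track with replicate aggregation
#'
#' Computes per-position MethScores for each replicate profile and
#' aggregates them: mean and sample standard deviation across replicates,
#' skipping replicates where the score is undefined. Positions undefined
#' in all replicates are omitted; the SD is NA with fewer than two
#' defined replicate scores.
#'
#' @param profiles list of `end_profile` replicates for one
#'   contig/strand.
#' @param flank,weights,denominator_mode,clamp passed to [methscore()].
#' @return data.frame: contig, pos, strand, methscore_mean, methscore_sd,
#'   n_replicates.
#' @export
methscore_track <- function(profiles, flank = 2L, weights = NULL,
                            denominator_mode = c("literal", "mean"),
                            clamp = TRUE) {
  denominator_mode <- match.arg(denominator_mode)
  stop_if_not(length(profiles) >= 1L, "need at least one replicate")
  ctg <- profiles[[1L]]$contig; strand <- profiles[[1L]]$strand
  L <- length(profiles[[1L]]$ends3)
  for (p in profiles)
    stop_if_not(p$contig == ctg && p$strand == strand &&
                  length(p$ends3) == L,
                "replicate profiles must share contig, strand and length")
  pos <- flank:(L - 1L - flank)
  mat <- vapply(profiles, function(p)
    methscore(p, pos, flank = flank, weights = weights,
              denominator_mode = denominator_mode, clamp = clamp),
    numeric(length(pos)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(pos))
  n_def <- as.integer(rowSums(!is.na(mat)))
  keep <- n_def > 0L
  means <- rowMeans(mat, na.rm = TRUE)
  sds <- apply(mat, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  })
  out <- data.frame(contig = ctg, pos = pos[keep], strand = strand,
                    methscore_mean = means[keep], methscore_sd = sds[keep],
                    n_replicates = n_def[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
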