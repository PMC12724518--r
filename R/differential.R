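# Presence/absence classification of Nm sites across the four isogenic
# conditions and orphan snoRNA target assignment.

.canonical_conditions <- c("CT2", "CT2-smDEL", "H9", "H9-smDEL")

#' Build a presence/absence matrix across conditions
#'
#' Rows are the union of (contig, pos, strand) positions over all
#' condition score tables; cells are `present` (score >= `present_min`),
#' `absent` (score <= `absent_max`) or `ambiguous`. A position missing
#' from a condition's table scores 0. Rows with no present cell are
#' dropped.
#'
#' Score tables should cover every union position with the condition's
#' actual Nm score (e.g. re-scored from its deduplicated coverage with
#' the internal scorer used by [run_diff()]), not just the positions that
#' passed site calling; otherwise sub-threshold but clearly nonzero
#' positions would be mistaken for absent.
#'
#' @param site_lists named list (condition label -> data.frame with
#'   columns contig, pos, strand, nm_score).
#' @param present_min minimum score for presence.
#' @param absent_max maximum score for absence; scores in between are
#'   ambiguous.
#' @return object of class `nm_presence_matrix`: list with `sites`
#'   (data.frame contig, pos, strand), `scores` and `states` (matrices,
#'   one column per condition) and `conditions`.
#' @export
build_matrix <- function(site_lists, present_min = 500, absent_max = 50) {
  conditions <- names(site_lists)
  stop_if_not(!is.null(conditions) && all(nzchar(conditions)),
              "site_lists must be a named list")
  if (anyDuplicated(conditions))
    stop("duplicate condition labels", call. = FALSE)
  stop_if_not(absent_max < present_min, "absent_max must be below present_min")

  all_pos <- unique(do.call(rbind, lapply(site_lists, function(d)
    d[, c("contig", "pos", "strand"), drop = FALSE])))
  all_pos <- all_pos[order(all_pos$contig, all_pos$pos, all_pos$strand), ,
                     drop = FALSE]
  rownames(all_pos) <- NULL
  key <- paste(all_pos$contig, all_pos$pos, all_pos$strand)
  scores <- sapply(site_lists, function(d) {
    i <- match(key, paste(d$contig, d$pos, d$strand))
    ifelse(is.na(i), 0, d$nm_score[i])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(key))
  colnames(scores) <- conditions
  states <- matrix("ambiguous", nrow = nrow(scores), ncol = ncol(scores),
                   dimnames = dimnames(scores))
  states[scores >= present_min] <- "present"
  states[scores <= absent_max] <- "absent"
  keep <- rowSums(states == "present") > 0L
  structure(list(sites = all_pos[keep, , drop = FALSE],
                 scores = scores[keep, , drop = FALSE],
                 states = states[keep, , drop = FALSE],
                 conditions = conditions),
            class = "nm_presence_matrix")
}

#' @export
print.nm_presence_matrix <- function(x, ...) {
  cat("nm_presence_matrix:", nrow(x$sites), "site(s) x",
      length(x$conditions), "conditions\n")
  invisible(x)
}

#' Classify sites by their presence pattern
#'
#' Maps each row's (CT2, CT2-smDEL, H9, H9-smDEL) pattern to a
#' differential class:
#'
#' * present only in CT2 -> `SNORD113114_candidate` (signal lost with the
#'   SNORD113/114 cluster, absent from both H9 lines);
#' * present in CT2 and H9, absent in both smDEL lines ->
#'   `SNORD116_candidate`;
#' * present everywhere -> `shared`;
#' * present in both CT2 lines only -> `CT2_specific`; in both H9 lines
#'   only -> `H9_specific`;
#' * any row containing an ambiguous cell, or any other pattern ->
#'   `unclassified`.
#'
#' @param pm an `nm_presence_matrix` built over the canonical four
#'   conditions.
#' @return data.frame: contig, pos, strand, class, plus one score column
#'   per condition.
#' @export
classify_sites <- function(pm) {
  stop_if_not(inherits(pm, "nm_presence_matrix"), "need an nm_presence_matrix")
  if (!identical(pm$conditions, .canonical_conditions))
    stop("matrix must be built over conditions ",
         paste(.canonical_conditions, collapse = ", "), call. = FALSE)
  patt <- apply(pm$states, 1L, function(s)
    paste(substr(s, 1L, 2L), collapse = ""))  # e.g. "prabprab"
  code <- c("prababab" = "SNORD113114_candidate",
            "prabprab" = "SNORD116_candidate",
            "prprprpr" = "shared",
            "prprabab" = "CT2_specific",
            "ababprpr" = "H9_specific")
  class <- unname(code[patt])
  class[is.na(class)] <- "unclassified"
  class[apply(pm$states, 1L, function(s) any(s == "ambiguous"))] <-
    "unclassified"
  out <- cbind(pm$sites,
               data.frame(class = class, stringsAsFactors = FALSE),
               as.data.frame(pm$scores))
  rownames(out) <- NULL
  out
}

#' Assign orphan snoRNA guides to differential candidate sites
#'
#' For each SNORD113/114- or SNORD116-candidate site, scans the matching
#' snoRNA family (only) for canonical guide matches with
#' [scan_targets()] and assigns the best-scoring one. Candidates without
#' a canonical family match keep their class but stay unassigned; sites
#' of other classes are never assigned.
#'
#' @param calls output of [classify_sites()].
#' @param snornas list of `snorna_model` objects; families are read from
#'   the id prefix (SNORD113, SNORD114, SNORD116, ...).
#' @param reference an `nm_reference`.
#' @param window,min_pairs,max_mismatches passed to [scan_targets()].
#' @return `calls` with columns assigned_snorna, ase_kind, duplex_score,
#'   n_pairs, n_gu_pairs, n_mismatches added.
#' @export
assign_targets <- function(calls, snornas, reference, window = 7L,
                           min_pairs = 9L, max_mismatches = 2L) {
  fams <- vapply(snornas, function(m) snorna_family(m$id), character(1))
  calls$assigned_snorna <- NA_character_
  calls$ase_kind <- NA_character_
  calls$duplex_score <- NA_integer_
  calls$n_pairs <- NA_integer_
  calls$n_gu_pairs <- NA_integer_
  calls$n_mismatches <- NA_integer_
  family_for <- list(SNORD113114_candidate = c("SNORD113", "SNORD114"),
                     SNORD116_candidate = "SNORD116")
  for (i in seq_len(nrow(calls))) {
    wanted <- family_for[[calls$class[i]]]
    if (is.null(wanted)) next
    pool <- snornas[fams %in% wanted]
    if (length(pool) == 0L) next
    hits <- scan_targets(pool, calls[i, c("contig", "pos", "strand")],
                         reference, window = window, min_pairs = min_pairs,
                         max_mismatches = max_mismatches)
    if (nrow(hits) == 0L) next
    best <- hits[1L, ]
    calls$assigned_snorna[i] <- best$snorna_id
    calls$ase_kind[i] <- best$ase_kind
    calls$duplex_score[i] <- best$duplex_score
    calls$n_pairs[i] <- best$n_pairs
    calls$n_gu_pairs[i] <- best$n_gu_pairs
    calls$n_mismatches[i] <- best$n_mismatches
  }
  calls
}
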