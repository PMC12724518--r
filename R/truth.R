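# Ground-truth modification sites across the four isogenic conditions.

.default_conditions <- c("CT2", "CT2-smDEL", "H9", "H9-smDEL")

#' Default truth-set design
#'
#' Site counts per dependency class, the tandem-pair layout and the
#' stoichiometry distribution used by [plant_truth()]. Stoichiometries
#' are drawn uniformly from `fraction_range` (default `[0.3, 1]`).
#'
#' @param constitutive,SNORD116,SNORD113114,cell_specific site counts.
#' @param tandem_pairs number of adjacent constitutive site pairs planted
#'   to exercise 3'-end masking.
#' @param tandem_distance distance (nt) between the members of a tandem
#'   pair; must not exceed the simulation trim budget for masking to act.
#' @param fraction_range range of the uniform stoichiometry distribution.
#' @param min_gap minimum spacing between non-tandem sites (nt), kept
#'   larger than the caller's flanking window.
#' @param margin minimum distance of any site from a transcript boundary.
#' @return list of design parameters.
#' @export
truth_design <- function(constitutive = 10L, SNORD116 = 4L,
                         SNORD113114 = 4L, cell_specific = 0L,
                         tandem_pairs = 1L, tandem_distance = 1L,
                         fraction_range = c(0.3, 1.0),
                         min_gap = 110L, margin = 120L) {
  d <- list(constitutive = constitutive, SNORD116 = SNORD116,
            SNORD113114 = SNORD113114, cell_specific = cell_specific,
            tandem_pairs = tandem_pairs, tandem_distance = tandem_distance,
            fraction_range = fraction_range, min_gap = min_gap,
            margin = margin)
  stop_if_not(all(unlist(d[1:4]) >= 0L), "class counts must be >= 0")
  stop_if_not(fraction_range[1] >= 0 && fraction_range[2] <= 1 &&
                fraction_range[1] <= fraction_range[2],
              "fraction_range must be within [0, 1]")
  d
}

#' Choose well-separated site positions inside transcripts
#'
#' Samples positions uniformly within transcript bodies, at least
#' `margin` nt from transcript boundaries and `min_gap` nt apart (also
#' from any position in `avoid`). Deterministic for a fixed seed.
#'
#' @param reference an `nm_reference`.
#' @param n number of positions.
#' @param min_gap,margin spacing constraints (nt).
#' @param avoid optional data.frame (contig, pos, strand) of positions new
#'   sites must keep `min_gap` away from.
#' @param seed integer seed.
#' @return data.frame contig, pos, strand (the host transcript's strand).
#' @export
choose_site_positions <- function(reference, n, min_gap = 110L,
                                  margin = 120L, avoid = NULL, seed = 1L) {
  if (n == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  tx <- reference$transcripts
  tx <- tx[(tx$end - tx$start) > 2L * margin + 10L, , drop = FALSE]
  stop_if_not(nrow(tx) > 0L, "no transcript long enough for the margins")
  withr::with_seed(seed, {
    chosen <- if (is.null(avoid)) {
      data.frame(contig = character(0), pos = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    } else {
      avoid[, c("contig", "pos", "strand"), drop = FALSE]
    }
    n_keep_from <- nrow(chosen)
    tries <- 0L
    while (nrow(chosen) < n_keep_from + n) {
      tries <- tries + 1L
      if (tries > 50000L)
        stop("could not place ", n, " sites with min_gap ", min_gap,
             call. = FALSE)
      k <- sample.int(nrow(tx), 1L)
      pos <- sample((tx$start[k] + margin):(tx$end[k] - margin - 1L), 1L)
      same <- chosen$contig == tx$contig[k]
      if (any(same & abs(chosen$pos - pos) < min_gap)) next
      chosen <- rbind(chosen, data.frame(contig = tx$contig[k], pos = pos,
                                         strand = tx$strand[k],
                                         stringsAsFactors = FALSE))
    }
  })
  out <- chosen[(n_keep_from + 1L):nrow(chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plant ground-truth Nm sites
#'
#' Builds a truth set over the four isogenic conditions (CT2, CT2-smDEL,
#' H9, H9-smDEL). snoRNA-dependent sites are placed at the design targets
#' of the supplied snoRNAs, matched by family: SNORD116-family guides are
#' expressed in CT2 and H9 but deleted in both smDEL lines; SNORD113/114
#' -family guides are expressed only in CT2. Constitutive sites carry no
#' guide and are present everywhere; cell-specific sites are present in
#' one cell line's two conditions. At least one adjacent (tandem) site
#' pair is planted by default to exercise 3'-end masking.
#'
#' @param reference an `nm_reference`.
#' @param snornas list of `snorna_model` objects with design targets
#'   (from [design_snornas()]); families are read from the id prefix.
#' @param design a [truth_design()] list.
#' @param seed integer seed.
#' @return object of class `nm_truth`: list with `sites` (data.frame:
#'   site_id, contig, pos, strand, fraction, dependency, guide_snorna,
#'   cell, tandem, tandem_group), `conditions` and `expressed_snornas`
#'   (named list: condition -> snoRNA ids).
#' @export
plant_truth <- function(reference, snornas = list(), design = truth_design(),
                        seed = 1L) {
  fams <- vapply(snornas, function(m) snorna_family(m$id), character(1))
  ids <- vapply(snornas, function(m) m$id, character(1))
  need <- c(SNORD116 = design$SNORD116,
            SNORD113114 = design$SNORD113114)
  have <- c(SNORD116 = sum(fams == "SNORD116"),
            SNORD113114 = sum(fams %in% c("SNORD113", "SNORD114")))
  if (any(need > have))
    stop("more snoRNA-dependent sites requested than designed snoRNAs (",
         paste(names(need)[need > have], collapse = ", "), ")", call. = FALSE)

  dep_rows <- list()
  take <- function(idx, dependency, k) {
    idx <- idx[seq_len(k)]
    do.call(rbind, lapply(idx, function(i) {
      tg <- snornas[[i]]$target
      stop_if_not(!is.null(tg), "snoRNA lacks a design target")
      data.frame(contig = tg$contig, pos = tg$pos, strand = tg$strand,
                 dependency = dependency, guide_snorna = ids[i],
                 stringsAsFactors = FALSE)
    }))
  }
  if (design$SNORD116 > 0L)
    dep_rows$s116 <- take(which(fams == "SNORD116"), "SNORD116",
                          design$SNORD116)
  if (design$SNORD113114 > 0L)
    dep_rows$s113 <- take(which(fams %in% c("SNORD113", "SNORD114")),
                          "SNORD113114", design$SNORD113114)
  dep <- if (length(dep_rows)) do.call(rbind, dep_rows) else NULL

  n_free <- design$constitutive + design$cell_specific + design$tandem_pairs
  free <- choose_site_positions(reference, n_free, min_gap = design$min_gap,
                                margin = design$margin, avoid = dep,
                                seed = sub_seed(seed, 1L))
  sites <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), dependency = character(0),
                      guide_snorna = character(0), stringsAsFactors = FALSE)
  if (!is.null(dep)) sites <- dep
  idx <- 0L
  add_free <- function(k, dependency) {
    if (k == 0L) return(NULL)
    rows <- free[(idx + 1L):(idx + k), , drop = FALSE]
    idx <<- idx + k
    rows$dependency <- dependency
    rows$guide_snorna <- NA_character_
    rows
  }
  sites <- rbind(sites, add_free(design$constitutive, "constitutive"))
  cs <- add_free(design$cell_specific, "cell_specific")
  sites <- rbind(sites, cs)

  # Tandem pairs: two adjacent constitutive sites; the genomically planted
  # pair is oriented so both members sit inside the host transcript.
  tandem_group <- rep(NA_integer_, nrow(sites))
  sites$cell <- NA_character_
  if (!is.null(cs) && nrow(cs) > 0L)
    sites$cell[sites$dependency == "cell_specific"] <-
      rep(c("CT2", "H9"), length.out = nrow(cs))
  if (design$tandem_pairs > 0L) {
    anchors <- free[(idx + 1L):(idx + design$tandem_pairs), , drop = FALSE]
    for (g in seq_len(nrow(anchors))) {
      a <- anchors[g, ]
      pair <- data.frame(contig = a$contig,
                         pos = c(a$pos, a$pos + design$tandem_distance),
                         strand = a$strand, dependency = "constitutive",
                         guide_snorna = NA_character_,
                         cell = NA_character_, stringsAsFactors = FALSE)
      sites <- rbind(sites, pair)
      tandem_group <- c(tandem_group, rep(g, 2L))
    }
  }
  sites$tandem <- !is.na(tandem_group)
  sites$tandem_group <- tandem_group

  withr::with_seed(sub_seed(seed, 2L), {
    sites$fraction <- stats::runif(nrow(sites), design$fraction_range[1],
                                   design$fraction_range[2])
  })
  sites$site_id <- sprintf("site%03d", seq_len(nrow(sites)))
  sites <- sites[, c("site_id", "contig", "pos", "strand", "fraction",
                     "dependency", "guide_snorna", "cell", "tandem",
                     "tandem_group")]
  rownames(sites) <- NULL

  # Genotypes: both smDEL lines lose the paternal SNORD116 cluster; the
  # CT2-smDEL line additionally silences the imprinted chr14q32
  # SNORD113/114 clusters, which the H9 background never expresses, so
  # SNORD113/114 guides are active in CT2 only.
  expressed <- list(
    "CT2"       = ids,
    "CT2-smDEL" = ids[!(fams %in% c("SNORD113", "SNORD114", "SNORD116"))],
    "H9"        = ids[!(fams %in% c("SNORD113", "SNORD114"))],
    "H9-smDEL"  = ids[!(fams %in% c("SNORD113", "SNORD114", "SNORD116"))])

  structure(list(sites = sites, conditions = .default_conditions,
                 expressed_snornas = expressed),
            class = "nm_truth")
}

#' @export
print.nm_truth <- function(x, ...) {
  cat("nm_truth:", nrow(x$sites), "site(s) across",
      length(x$conditions), "conditions\n")
  print(table(x$sites$dependency))
  invisible(x)
}

#' Construct a truth set from an explicit site table
#'
#' Lower-level companion to [plant_truth()] for studies that need exact
#' stoichiometries or site layouts. Missing optional columns
#' (guide_snorna, cell, tandem, tandem_group, site_id) are filled with
#' defaults.
#'
#' @param sites data.frame with at least contig, pos, strand, fraction,
#'   dependency.
#' @param conditions ordered condition labels.
#' @param expressed_snornas named list: condition -> expressed snoRNA ids.
#' @return an `nm_truth`.
#' @export
nm_truth <- function(sites, conditions = .default_conditions,
                     expressed_snornas = NULL) {
  stop_if_not(!anyDuplicated(conditions), "condition labels must be unique")
  stop_if_not(all(sites$fraction >= 0 & sites$fraction <= 1),
              "fractions must lie in [0, 1]")
  n <- nrow(sites)
  if (is.null(sites$guide_snorna)) sites$guide_snorna <- rep(NA_character_, n)
  if (is.null(sites$cell)) sites$cell <- rep(NA_character_, n)
  if (is.null(sites$tandem)) sites$tandem <- rep(FALSE, n)
  if (is.null(sites$tandem_group)) sites$tandem_group <- rep(NA_integer_, n)
  if (is.null(sites$site_id)) sites$site_id <- sprintf("site%03d",
                                                       seq_len(nrow(sites)))
  dep_class <- sites$dependency %in% c("SNORD116", "SNORD113114")
  stop_if_not(all(is.na(sites$guide_snorna) | dep_class),
              "guide_snorna may only be set for snoRNA-dependent sites")
  if (is.null(expressed_snornas))
    expressed_snornas <- stats::setNames(
      rep(list(character(0)), length(conditions)), conditions)
  structure(list(sites = sites, conditions = conditions,
                 expressed_snornas = expressed_snornas),
            class = "nm_truth")
}

#' Effective methylation fractions in a condition
#'
#' A site's effective stoichiometry is its planted fraction, zeroed when
#' its guide snoRNA is not expressed in the condition (snoRNA-dependent
#' classes) or when the condition belongs to the other cell line
#' (cell-specific sites).
#'
#' @param truth an `nm_truth`.
#' @param condition one of the truth set's condition labels.
#' @return numeric vector aligned with `truth$sites`.
#' @export
effective_fractions <- function(truth, condition) {
  stop_if_not(condition %in% truth$conditions,
              paste0("unknown condition: ", condition))
  s <- truth$sites
  f <- s$fraction
  expressed <- truth$expressed_snornas[[condition]]
  dep <- !is.na(s$guide_snorna)
  f[dep & !(s$guide_snorna %in% expressed)] <- 0
  cell_line <- sub("-smDEL$", "", condition)
  cs <- s$dependency == "cell_specific"
  f[cs & !is.na(s$cell) & s$cell != cell_line] <- 0
  f
}
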