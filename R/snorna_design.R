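# Designed box C/D snoRNAs: fixed scaffold segments chosen to be free of
# accidental RUGAUGA / CUGA instances (the spacer and tail contain no G).
.sno_leader <- "UUCCAUU"
.sno_boxC   <- "AUGAUGA"
.sno_spacer <- "CCAUUCCAAUCCAUU"
.sno_boxD   <- "CUGA"
.sno_tail   <- "CCAAUU"

#' Design box C/D snoRNAs against chosen target positions
#'
#' Each designed snoRNA carries a box C (RUGAUGA) near its 5' end, a box D
#' (CUGA) near its 3' end, and an antisense element (ASE) immediately 5'
#' of box D that is the exact reverse complement of the target window.
#' The window is placed so that the canonical D+5 rule (the target
#' nucleotide paired with the snoRNA nucleotide five positions upstream of
#' box D is the methylated one) maps exactly to the requested position:
#' on the plus strand the window starts at `pos - 4`, on the minus strand
#' at `pos - guide_length + 5`.
#'
#' @param reference an `nm_reference`.
#' @param targets data.frame with columns contig, pos (0-based), strand.
#'   One snoRNA is designed per row; duplicate rows give independent
#'   guides for the same site.
#' @param guide_length ASE length in nucleotides, between 10 and 15.
#' @param ids optional character vector of snoRNA identifiers; defaults to
#'   SNO001, SNO002, ... Family-aware identifiers (e.g. "SNORD116-1") are
#'   used by [plant_truth()] and [assign_targets()].
#' @return list of `snorna_model` objects (id, seq in the RNA alphabet,
#'   boxes, ases, target).
#' @export
design_snornas <- function(reference, targets, guide_length = 12L, ids = NULL) {
  stop_if_not(guide_length >= 10L && guide_length <= 15L,
              "guide_length must be in [10, 15]")
  if (is.null(targets) || nrow(targets) == 0L) return(list())
  if (is.null(ids)) ids <- sprintf("SNO%03d", seq_len(nrow(targets)))
  stop_if_not(length(ids) == nrow(targets), "one id per target row required")

  lapply(seq_len(nrow(targets)), function(i) {
    ctg <- targets$contig[i]; pos <- targets$pos[i]; strand <- targets$strand[i]
    stop_if_not(strand %in% c("+", "-"), "strand must be + or -")
    L <- guide_length
    t0 <- if (strand == "+") pos - 4L else pos - L + 5L
    window <- contig_window(reference, ctg, t0, t0 + L)
    if (grepl("N", window, fixed = TRUE))
      stop("target window for ", ids[i], " contains N", call. = FALSE)
    # Transcript-oriented target sequence, then its reverse complement.
    target_rna <- if (strand == "+") to_rna(window) else revcomp_rna(window)
    ase <- revcomp_rna(target_rna)
    seq <- paste0(.sno_leader, .sno_boxC, .sno_spacer, ase, .sno_boxD, .sno_tail)
    model <- snorna_model(ids[i], seq, ase_length = L)
    model$target <- data.frame(contig = ctg, pos = pos, strand = strand,
                               stringsAsFactors = FALSE)
    model
  })
}

#' Construct a snoRNA model from a sequence
#'
#' Locates box motifs with [find_boxes()] and antisense elements with
#' [extract_ases()].
#'
#' @param id snoRNA identifier.
#' @param seq sequence (RNA or DNA alphabet; T is read as U).
#' @param ase_length ASE length used for extraction (10-15).
#' @return object of class `snorna_model`.
#' @export
snorna_model <- function(id, seq, ase_length = 12L) {
  seq <- to_rna(seq)
  boxes <- find_boxes(seq)
  model <- structure(list(id = id, seq = seq, boxes = boxes,
                          ases = NULL, target = NULL),
                     class = "snorna_model")
  model$ases <- extract_ases(model, ase_length = ase_length)$ases
  model
}

#' @export
print.snorna_model <- function(x, ...) {
  cat("snorna_model", x$id, "-", nchar(x$seq), "nt;",
      nrow(x$boxes), "box motif(s),",
      if (is.null(x$ases)) 0L else nrow(x$ases), "ASE(s)\n")
  invisible(x)
}

# Family prefix of a snoRNA id: "SNORD116-12" -> "SNORD116".
snorna_family <- function(id) sub("[-_.].*$", "", id)
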