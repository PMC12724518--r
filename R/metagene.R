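# Transcript-region assignment of Nm sites, metagene summaries and CLASH
# chimera intersection.

#' Load transcript annotation
#'
#' Reads GTF (exon and CDS features, grouped by `transcript_id`) or BED12
#' (blocks as exons, the thick interval as CDS). GTF's 1-based closed
#' coordinates are converted to the package's 0-based half-open
#' convention. Transcripts whose CDS falls outside their exons are
#' skipped with a warning.
#'
#' @param path GTF (.gtf) or BED12 (.bed) file.
#' @param format "auto" (by extension), "gtf" or "bed12".
#' @return object of class `transcript_models`: list of transcripts, each
#'   a list with id, contig, strand, `exons` (data.frame start, end,
#'   0-based half-open, sorted) and `cds` (length-2 vector or NULL).
#' @export
load_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    df$start0 <- df$start - 1L  # to 0-based half-open
    models <- lapply(split(df, df$transcript_id), function(d) {
      ex <- d[d$type == "exon", , drop = FALSE]
      if (nrow(ex) == 0L) return(NULL)
      ex <- ex[order(ex$start0), , drop = FALSE]
      cds_rows <- d[d$type == "CDS", , drop = FALSE]
      cds <- NULL
      if (nrow(cds_rows) > 0L)
        cds <- c(min(cds_rows$start0), max(cds_rows$end))
      list(id = d$transcript_id[1L], contig = as.character(d$seqnames[1L]),
           strand = as.character(d$strand[1L]),
           exons = data.frame(start = ex$start0, end = ex$end),
           cds = cds)
    })
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    models <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- S4Vectors::mcols(g)$blocks
      ex <- if (!is.null(blocks)) {
        b <- blocks[[1L]]
        data.frame(start = GenomicRanges::start(g) - 1L +
                     BiocGenerics::start(b) - 1L,
                   end = GenomicRanges::start(g) - 1L + BiocGenerics::end(b))
      } else {
        data.frame(start = GenomicRanges::start(g) - 1L,
                   end = GenomicRanges::end(g))
      }
      thick <- S4Vectors::mcols(g)$thick
      cds <- NULL
      if (!is.null(thick) && BiocGenerics::width(thick)[1L] > 0L)
        cds <- c(BiocGenerics::start(thick)[1L] - 1L,
                 BiocGenerics::end(thick)[1L])
      list(id = S4Vectors::mcols(g)$name %||% paste0("tx", i),
           contig = as.character(GenomicRanges::seqnames(g)),
           strand = as.character(GenomicRanges::strand(g)),
           exons = ex, cds = cds)
    })
  }
  models <- Filter(Negate(is.null), models)
  ok <- vapply(models, function(m) {
    if (is.null(m$cds)) return(TRUE)
    inside <- any(m$exons$start <= m$cds[1L] & m$exons$end >= m$cds[1L] + 1L) &&
      any(m$exons$start <= m$cds[2L] - 1L & m$exons$end >= m$cds[2L])
    if (!inside) warning("CDS outside exons; skipping transcript ", m$id)
    inside
  }, logical(1))
  structure(unname(models[ok]), class = "transcript_models")
}

#' Transcript models from a synthetic reference
#'
#' @param reference an `nm_reference`.
#' @return a `transcript_models` object (single-exon transcripts).
#' @export
as_transcript_models <- function(reference) {
  tx <- reference$transcripts
  structure(lapply(seq_len(nrow(tx)), function(i) {
    list(id = tx$transcript_id[i], contig = tx$contig[i],
         strand = tx$strand[i],
         exons = data.frame(start = tx$start[i], end = tx$end[i]),
         cds = c(tx$cds_start[i], tx$cds_end[i]))
  }), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", length(x), "transcript(s)\n")
  invisible(x)
}

# Genomic position -> transcript coordinate (0-based; NA if not exonic).
genomic_to_tx <- function(model, gpos) {
  ex <- model$exons
  widths <- ex$end - ex$start
  before <- c(0L, cumsum(widths))[-(nrow(ex) + 1L)]
  hit <- which(ex$start <= gpos & gpos < ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  plus_pos <- before[hit[1L]] + (gpos - ex$start[hit[1L]])
  if (model$strand == "+") plus_pos else sum(widths) - 1L - plus_pos
}

# 5'UTR / CDS / 3'UTR lengths in transcript coordinates (NULL if no CDS).
tx_segments <- function(model) {
  widths <- model$exons$end - model$exons$start
  txlen <- sum(widths)
  if (is.null(model$cds)) return(list(txlen = txlen, seg = NULL))
  a <- genomic_to_tx(model, model$cds[1L])
  b <- genomic_to_tx(model, model$cds[2L] - 1L)
  lo <- min(a, b); hi <- max(a, b)
  list(txlen = txlen,
       seg = c(utr5 = lo, cds = hi - lo + 1L, utr3 = txlen - hi - 1L))
}

#' Assign Nm sites to transcript regions
#'
#' Maps each site to the region (5'UTR, CDS, 3'UTR or noncoding exon) of
#' an overlapping same-strand transcript, together with a metagene
#' coordinate in `[0, 3)` (region index plus fractional position within
#' the region). When several transcripts overlap a site, the one with
#' the longest CDS wins. Intronic or intergenic sites are `unassigned`.
#'
#' @param sites data.frame with columns contig, pos, strand.
#' @param transcripts a `transcript_models` object.
#' @return data.frame: contig, pos, strand, region, transcript_id,
#'   metagene_coord.
#' @export
assign_region <- function(sites, transcripts) {
  out <- sites[, c("contig", "pos", "strand"), drop = FALSE]
  out$region <- "unassigned"
  out$transcript_id <- NA_character_
  out$metagene_coord <- NA_real_
  for (i in seq_len(nrow(sites))) {
    cands <- Filter(function(m) {
      m$contig == sites$contig[i] && m$strand == sites$strand[i] &&
        any(m$exons$start <= sites$pos[i] & sites$pos[i] < m$exons$end)
    }, transcripts)
    if (length(cands) == 0L) next
    cds_len <- vapply(cands, function(m)
      if (is.null(m$cds)) 0L else m$cds[2L] - m$cds[1L], integer(1))
    m <- cands[[which.max(cds_len)]]
    info <- tx_segments(m)
    txpos <- genomic_to_tx(m, sites$pos[i])
    out$transcript_id[i] <- m$id
    if (is.null(info$seg)) {
      out$region[i] <- "noncoding_exon"
      next
    }
    seg <- info$seg
    bounds <- cumsum(c(0L, seg))
    if (txpos < bounds[2L]) {
      out$region[i] <- "5UTR"
      out$metagene_coord[i] <- (txpos - bounds[1L]) / max(seg[1L], 1L)
    } else if (txpos < bounds[3L]) {
      out$region[i] <- "CDS"
      out$metagene_coord[i] <- 1 + (txpos - bounds[2L]) / max(seg[2L], 1L)
    } else {
      out$region[i] <- "3UTR"
      out$metagene_coord[i] <- 2 + (txpos - bounds[3L]) / max(seg[3L], 1L)
    }
  }
  rownames(out) <- NULL
  out
}

#' Metagene summary of region assignments
#'
#' Proportions of assigned sites per mRNA region (5'UTR, CDS, 3'UTR;
#' summing to 1 over those three) and a binned density of metagene
#' coordinates over `[0, 3)`. Unassigned and noncoding sites are
#' excluded from the denominator and reported separately.
#'
#' @param assignments output of [assign_region()].
#' @param bins_per_region histogram bins per region (default 30).
#' @return list with `proportions` (named numeric), `counts`, `density`
#'   (data.frame bin_start, bin_end, count), `n_assigned`, `n_unassigned`,
#'   `n_noncoding`.
#' @export
metagene_summary <- function(assignments, bins_per_region = 30L) {
  coding <- assignments[assignments$region %in% c("5UTR", "CDS", "3UTR"), ,
                        drop = FALSE]
  if (nrow(coding) == 0L)
    stop("no sites assigned to mRNA regions", call. = FALSE)
  counts <- c("5UTR" = sum(coding$region == "5UTR"),
              "CDS" = sum(coding$region == "CDS"),
              "3UTR" = sum(coding$region == "3UTR"))
  breaks <- seq(0, 3, length.out = 3L * bins_per_region + 1L)
  h <- graphics::hist(coding$metagene_coord, breaks = breaks, plot = FALSE)
  list(proportions = counts / sum(counts), counts = counts,
       density = data.frame(bin_start = breaks[-length(breaks)],
                            bin_end = breaks[-1L], count = h$counts),
       n_assigned = nrow(coding),
       n_unassigned = sum(assignments$region == "unassigned"),
       n_noncoding = sum(assignments$region == "noncoding_exon"))
}

#' Intersect Nm sites with CLASH chimera fragments
#'
#' A site overlaps a fragment when its position lies in the fragment's
#' half-open interval on the same contig. Strand is ignored by default
#' (chimera fragment strand conventions vary); set `same_strand = TRUE`
#' to require matching strands. One output row per overlapping
#' (site, fragment) pair.
#'
#' @param sites data.frame with columns contig, pos, strand.
#' @param chimera data.frame with columns contig, start, end, snorna_id
#'   (and optionally strand), or the path to a BED file whose name field
#'   carries the snoRNA id.
#' @param same_strand require matching strand (default FALSE).
#' @return data.frame: contig, pos, strand, snorna_id, fragment_start,
#'   fragment_end.
#' @export
intersect_clash <- function(sites, chimera, same_strand = FALSE) {
  if (is.character(chimera)) chimera <- read_chimera_bed(chimera)
  s_gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(sites$pos + 1L, width = 1L),
    strand = sites$strand)
  f_gr <- GenomicRanges::GRanges(
    chimera$contig,
    IRanges::IRanges(chimera$start + 1L, chimera$end),
    strand = if ("strand" %in% names(chimera)) chimera$strand else "*")
  ov <- GenomicRanges::findOverlaps(s_gr, f_gr,
                                    ignore.strand = !same_strand)
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  out <- data.frame(contig = sites$contig[i], pos = sites$pos[i],
                    strand = sites$strand[i],
                    snorna_id = chimera$snorna_id[j],
                    fragment_start = chimera$start[j],
                    fragment_end = chimera$end[j],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# BED reader for chimera fragments with per-line validation (field count
# and coordinate sanity), so malformed lines are reported by number.
read_chimera_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L]))) ||
        as.integer(f[2L]) >= as.integer(f[3L]))
      stop("malformed BED line ", i, " in ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             snorna_id = S4Vectors::mcols(gr)$name,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
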