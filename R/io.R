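# Readers and writers for the package's on-disk formats. All interval
# output is 0-based half-open (BED convention); GTF output is 1-based.

#' Write the reference as FASTA and GTF
#'
#' @param reference an `nm_reference`.
#' @param fasta_path,gtf_path output files.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(reference$contigs, fasta_path)
  tx <- reference$transcripts
  gene_attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                       tx$transcript_id, tx$transcript_id)
  lines <- c(
    sprintf("%s\tnmseq\texon\t%d\t%d\t.\t%s\t.\t%s",
            tx$contig, tx$start + 1L, tx$end, tx$strand, gene_attr),
    sprintf("%s\tnmseq\tCDS\t%d\t%d\t.\t%s\t0\t%s",
            tx$contig, tx$cds_start + 1L, tx$cds_end, tx$strand, gene_attr))
  writeLines(lines, gtf_path)
  invisible(c(fasta_path, gtf_path))
}

#' Read a reference FASTA (without annotation)
#'
#' @param fasta_path FASTA file.
#' @param gtf_path optional GTF whose exon features become single-block
#'   transcript rows.
#' @return an `nm_reference` (transcripts empty unless a GTF is given).
#' @export
read_reference <- function(fasta_path, gtf_path = NULL) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  tx <- data.frame(transcript_id = character(0), contig = character(0),
                   strand = character(0), start = integer(0),
                   end = integer(0), cds_start = integer(0),
                   cds_end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(gtf_path)) {
    models <- load_annotation(gtf_path, format = "gtf")
    tx <- do.call(rbind, lapply(models, function(m) {
      data.frame(transcript_id = m$id, contig = m$contig, strand = m$strand,
                 start = min(m$exons$start), end = max(m$exons$end),
                 cds_start = if (is.null(m$cds)) NA_integer_ else m$cds[1L],
                 cds_end = if (is.null(m$cds)) NA_integer_ else m$cds[2L],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(contigs = contigs, transcripts = tx), class = "nm_reference")
}

#' Write snoRNA models as FASTA
#'
#' @param snornas list of `snorna_model` objects.
#' @param path output FASTA.
#' @export
write_snorna_fasta <- function(snornas, path) {
  seqs <- Biostrings::RNAStringSet(vapply(snornas, `[[`, character(1), "seq"))
  names(seqs) <- vapply(snornas, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read snoRNA models from FASTA
#'
#' Boxes and antisense elements are re-located on read, so any box C/D
#' snoRNA FASTA (T or U alphabet) can be scanned.
#'
#' @param path FASTA file.
#' @param ase_length ASE length passed to [extract_ases()].
#' @return list of `snorna_model` objects.
#' @export
read_snorna_fasta <- function(path, ase_length = 12L) {
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i)
    snorna_model(names(seqs)[i], as.character(seqs[[i]]),
                 ase_length = ase_length))
}

#' Write / read the ground-truth site table
#'
#' Tab-separated columns: site_id, contig, pos, strand, fraction,
#' dependency, guide_snorna, cell, tandem, tandem_group.
#'
#' @param truth an `nm_truth`.
#' @param path TSV file.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write aligned 3'-end records as BED6
#'
#' Each record is written as its aligned read span: for a plus-strand
#' read the 3' end is `end - 1`, for a minus-strand read it is `start`.
#' The name field carries the UMI and the score field the mean base
#' quality, so the full record round-trips through standard BED.
#'
#' @param records data.frame of aligned 3'-end records.
#' @param path output BED (gzip when the path ends in .gz).
#' @export
write_records_bed <- function(records, path) {
  start <- ifelse(records$strand == "+",
                  pmax(records$end3 - records$read_length + 1L, 0L),
                  records$end3)
  end <- ifelse(records$strand == "+", records$end3 + 1L,
                records$end3 + records$read_length)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", records$contig, start, end,
                   records$umi, format(records$mean_quality, trim = TRUE),
                   records$strand)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read aligned 3'-end records from BED6
#'
#' Inverse of [write_records_bed()]: the 3' end and read length are
#' recovered from the interval and strand.
#'
#' @param path BED6 file (.gz accepted).
#' @return data.frame of aligned 3'-end records.
#' @export
read_records_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(empty_records())
  start0 <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             end3 = ifelse(strand == "+", end - 1L, start0),
             umi = S4Vectors::mcols(gr)$name,
             read_length = end - start0,
             mean_quality = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write 3'-end coverage as bedGraph (one file per strand)
#'
#' @param coverage an `end_coverage`.
#' @param prefix output prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @return invisibly, the paths written.
#' @export
write_coverage_bedgraph <- function(coverage, prefix) {
  cc <- coverage$counts
  paths <- character(0)
  for (s in c("+", "-")) {
    d <- cc[cc$strand == s, , drop = FALSE]
    path <- paste0(prefix, if (s == "+") ".plus" else ".minus", ".bedgraph")
    writeLines(sprintf("%s\t%d\t%d\t%d", d$contig, d$pos, d$pos + 1L,
                       d$count), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Read a pair of per-strand coverage bedGraphs back into an end_coverage.
read_coverage_bedgraph <- function(prefix) {
  rows <- list()
  for (s in c("+", "-")) {
    path <- paste0(prefix, if (s == "+") ".plus" else ".minus", ".bedgraph")
    if (!file.exists(path) || length(readLines(path, n = 1L)) == 0L) next
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) next
    rows[[s]] <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                            strand = s,
                            pos = BiocGenerics::start(gr) - 1L,
                            count = as.integer(S4Vectors::mcols(gr)$score),
                            stringsAsFactors = FALSE)
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), strand = character(0),
               pos = integer(0), count = integer(0), stringsAsFactors = FALSE)
  counts <- counts[order(counts$contig, counts$strand, counts$pos), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, library_size = sum(counts$count)),
            class = "end_coverage")
}

#' Write called sites as TSV and BED6
#'
#' The BED score column holds the Nm score clamped to integer (BED
#' convention); the TSV keeps exact scores.
#'
#' @param sites data.frame of called sites.
#' @param tsv_path,bed_path output files (either may be NULL).
#' @export
write_sites <- function(sites, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(sites, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$contig, sites$pos,
                     sites$pos + 1L,
                     paste0("site_", seq_len(nrow(sites))),
                     as.integer(pmin(sites$nm_score, .Machine$integer.max)),
                     sites$strand)
    writeLines(lines, bed_path)
  }
  invisible(NULL)
}

#' @rdname write_sites
#' @param path sites TSV written by `write_sites()`.
#' @export
read_sites_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an end profile as a pair of bedGraph files
#'
#' Two files per profile: 5' ends and 3' ends; zero positions are
#' omitted.
#'
#' @param profile an `end_profile`.
#' @param prefix output prefix; writes `<prefix>.ends5.bedgraph` and
#'   `<prefix>.ends3.bedgraph`.
#' @export
write_profile_bedgraph <- function(profile, prefix) {
  for (what in c("ends5", "ends3")) {
    v <- profile[[what]]
    nz <- which(v > 0L) - 1L
    writeLines(sprintf("%s\t%d\t%d\t%d", profile$contig, nz, nz + 1L,
                       v[nz + 1L]),
               paste0(prefix, ".", what, ".bedgraph"))
  }
  invisible(prefix)
}

#' Read an end profile from a pair of bedGraph files
#'
#' @param prefix prefix used by [write_profile_bedgraph()].
#' @param contig,strand,length profile location and contig length.
#' @param replicate_id replicate label.
#' @return an `end_profile`.
#' @export
read_profile_bedgraph <- function(prefix, contig, strand, length,
                                  replicate_id = 1L) {
  vecs <- lapply(c("ends5", "ends3"), function(what) {
    v <- integer(length)
    path <- paste0(prefix, ".", what, ".bedgraph")
    if (file.size(path) > 0L) {
      gr <- rtracklayer::import(path, format = "bedGraph")
      gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
      v[BiocGenerics::start(gr)] <- as.integer(S4Vectors::mcols(gr)$score)
    }
    v
  })
  end_profile(contig, strand, replicate_id, ends5 = vecs[[1L]],
              ends3 = vecs[[2L]])
}
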