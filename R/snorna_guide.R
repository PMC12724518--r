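# Box C/D motif discovery, antisense elements, duplex scoring and the
# canonical D+5 targeting rule.

.box_c_pattern <- "(?=[AG]UGAUGA)"
.box_d_pattern <- "(?=CUGA)"

overlapping_matches <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based starts
}

#' Locate box C/D motifs in a snoRNA sequence
#'
#' Finds all RUGAUGA (box C family) and CUGA (box D family) instances and
#' flags the canonical assignment: the 5'-most RUGAUGA as box C and the
#' 3'-most CUGA as box D, with internal instances reported as C'/D'
#' candidates. The canonical assignment requires C to start before D; if
#' either motif is missing (or the ordering fails), an empty table is
#' returned with a `diagnostic` attribute explaining why.
#'
#' @param seq snoRNA sequence, RNA or DNA alphabet (T read as U),
#'   length >= 20.
#' @return data.frame with columns kind (C, Cprime, Dprime, D), start
#'   (0-based) and seq, sorted by start; attribute `diagnostic` holds a
#'   message when no canonical assignment exists.
#' @export
find_boxes <- function(seq) {
  seq <- to_rna(seq)
  stop_if_not(nchar(seq) >= 20L, "sequence must be at least 20 nt")
  c_starts <- overlapping_matches(seq, .box_c_pattern)
  d_starts <- overlapping_matches(seq, .box_d_pattern)

  empty <- function(msg) {
    out <- data.frame(kind = character(0), start = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- msg
    out
  }
  if (length(c_starts) == 0L) return(empty("no RUGAUGA (box C) instance found"))
  if (length(d_starts) == 0L) return(empty("no CUGA (box D) instance found"))
  c_start <- min(c_starts)
  d_start <- max(d_starts)
  if (c_start >= d_start)
    return(empty("box C does not precede box D; no canonical assignment"))

  # Internal candidates must fall strictly between box C and box D.
  cp <- c_starts[c_starts > c_start & c_starts + 7L <= d_start]
  dp <- d_starts[d_starts > c_start + 7L & d_starts < d_start]
  out <- data.frame(
    kind  = c("C", rep("Cprime", length(cp)), rep("Dprime", length(dp)), "D"),
    start = c(c_start, cp, dp, d_start),
    stringsAsFactors = FALSE)
  out$seq <- substring(seq, out$start + 1L,
                       out$start + ifelse(out$kind %in% c("C", "Cprime"), 7L, 4L))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract antisense elements upstream of box D / D'
#'
#' The ASE is the `ase_length` nucleotides ending immediately before the
#' box start. It is truncated (down to a minimum of 10 nt) when the
#' snoRNA 5' end intervenes; with fewer than 10 nt available no ASE is
#' reported for that box. When several D' candidates exist the 3'-most
#' one with sufficient upstream room is used.
#'
#' @param model a `snorna_model` (boxes already assigned).
#' @param ase_length requested ASE length, in [10, 15].
#' @return the model with its `ases` field set: data.frame with columns
#'   kind (D or Dprime), start, end (0-based half-open) and seq.
#' @export
extract_ases <- function(model, ase_length = 12L) {
  stop_if_not(ase_length >= 10L && ase_length <= 15L,
              "ase_length must be in [10, 15]")
  boxes <- model$boxes
  ases <- list()
  one_ase <- function(kind, box_start) {
    len <- min(ase_length, box_start)
    if (len < 10L) return(NULL)
    data.frame(kind = kind, start = box_start - len, end = box_start,
               seq = substring(model$seq, box_start - len + 1L, box_start),
               box_start = box_start, stringsAsFactors = FALSE)
  }
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    d <- boxes$start[boxes$kind == "D"]
    if (length(d) == 1L) ases$D <- one_ase("D", d)
    dp <- boxes$start[boxes$kind == "Dprime"]
    dp <- dp[dp >= 10L]
    if (length(dp) > 0L) ases$Dprime <- one_ase("Dprime", max(dp))
  }
  model$ases <- if (length(ases) > 0L) do.call(rbind, unname(ases)) else
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               seq = character(0), box_start = integer(0),
               stringsAsFactors = FALSE)
  rownames(model$ases) <- NULL
  model
}

.pair_kind <- local({
  kinds <- c(AU = "wc", UA = "wc", GC = "wc", CG = "wc",
             GU = "gu", UG = "gu")
  function(pair) {
    k <- unname(kinds[pair])
    k[is.na(k)] <- "mm"
    k
  }
})

#' Score an ungapped antiparallel RNA duplex
#'
#' Aligns two equal-length sequences antiparallel (the first base of
#' `ase_seq` against the last base of `target_seq`) and scores each
#' aligned pair: Watson-Crick (A:U, G:C) +2, G:U wobble +1, anything else
#' (including N) -2.
#'
#' This additive scheme ranks candidate duplexes and supports the
#' canonical-match filter; it is not a thermodynamic energy and its
#' values are not comparable to kcal/mol.
#'
#' @param ase_seq,target_seq equal-length sequences, both 5'->3'
#'   (RNA or DNA alphabet).
#' @return list with `pairing` (data.frame ase_offset, target_offset,
#'   kind), `n_pairs` (Watson-Crick pairs), `n_gu`, `n_mismatches` and
#'   `score`.
#' @export
duplex_score <- function(ase_seq, target_seq) {
  a <- strsplit(to_rna(ase_seq), "", fixed = TRUE)[[1]]
  t <- strsplit(to_rna(target_seq), "", fixed = TRUE)[[1]]
  if (length(a) != length(t))
    stop("duplex sequences must have equal length", call. = FALSE)
  L <- length(a)
  kind <- .pair_kind(paste0(a, rev(t)))
  n_wc <- sum(kind == "wc"); n_gu <- sum(kind == "gu"); n_mm <- sum(kind == "mm")
  list(pairing = data.frame(ase_offset = seq_len(L) - 1L,
                            target_offset = rev(seq_len(L)) - 1L,
                            kind = kind, stringsAsFactors = FALSE),
       n_pairs = n_wc, n_gu = n_gu, n_mismatches = n_mm,
       score = 2L * n_wc + n_gu - 2L * n_mm)
}

#' Predict the methylated target position under the D+5 rule
#'
#' For an ungapped antiparallel duplex between an ASE ending at
#' `box_start - 1` and a target window `[target_start, target_start + L)`,
#' the guide nucleotide is the snoRNA position `box_start - 5`; the
#' target base paired with it is the predicted Nm site. On the plus
#' strand the last ASE base pairs the window's genomic start, so the
#' prediction is `target_start + 4`; on the minus strand it mirrors to
#' `target_start + L - 5`. No prediction is made when the pairing does
#' not cover the guide nucleotide (ASE shorter than 5 nt).
#'
#' @param ase_start,box_start 0-based snoRNA offsets of the ASE start and
#'   of the box D/D' start (the ASE ends at `box_start`).
#' @param target_start genomic start (0-based) of the paired window.
#' @param target_length window length (equals the ASE length).
#' @param strand "+" or "-".
#' @return integer genomic position, or NA when the rule is unsatisfiable.
#' @export
predict_nm_position <- function(ase_start, box_start, target_start,
                                target_length, strand) {
  guide <- box_start - 5L
  out <- ifelse(strand == "+", target_start + 4L,
                target_start + target_length - 5L)
  out[guide < ase_start | target_length < 5L] <- NA_integer_
  as.integer(out)
}

#' Scan Nm sites for canonical snoRNA guides
#'
#' For every site and every antisense element, slides the ASE over the
#' region around the site (windows overlapping site +/- `window` nt) and
#' keeps ungapped antiparallel placements satisfying the duplex
#' constraints (at least `min_pairs` paired positions counting G:U, at
#' most `max_mismatches` mismatches) whose D+5 prediction equals the
#' observed site exactly.
#'
#' @param snornas list of `snorna_model` objects.
#' @param nm_sites data.frame with columns contig, pos, strand.
#' @param reference an `nm_reference` providing sequence context.
#' @param window half-width of the site region searched (nt).
#' @param min_pairs minimum paired positions (Watson-Crick + G:U).
#' @param max_mismatches maximum mismatching positions.
#' @return data.frame of guide matches sorted by duplex score
#'   (descending): snorna_id, ase_kind, contig, strand, target_start,
#'   target_end, n_pairs, n_gu_pairs, n_mismatches, duplex_score,
#'   predicted_nm_pos, site_pos.
#' @export
scan_targets <- function(snornas, nm_sites, reference, window = 7L,
                         min_pairs = 9L, max_mismatches = 2L) {
  out <- list()
  for (i in seq_len(nrow(nm_sites))) {
    ctg <- nm_sites$contig[i]; pos <- nm_sites$pos[i]
    strand <- nm_sites$strand[i]
    Lc <- contig_length(reference, ctg)
    for (model in snornas) {
      ases <- model$ases
      if (is.null(ases) || nrow(ases) == 0L) next
      for (j in seq_len(nrow(ases))) {
        L <- ases$end[j] - ases$start[j]
        t_lo <- pos - window - L + 1L
        t_hi <- pos + window
        if (t_lo < 0L || t_hi + L > Lc) {
          warning("site ", ctg, ":", pos, " too close to contig edge; skipped")
          next
        }
        for (t0 in t_lo:t_hi) {
          win <- contig_window(reference, ctg, t0, t0 + L)
          target_rna <- if (strand == "+") to_rna(win) else revcomp_rna(win)
          pred <- predict_nm_position(ases$start[j], ases$box_start[j],
                                      t0, L, strand)
          if (is.na(pred) || pred != pos) next
          d <- duplex_score(ases$seq[j], target_rna)
          if (d$n_pairs + d$n_gu < min_pairs || d$n_mismatches > max_mismatches)
            next
          out[[length(out) + 1L]] <- data.frame(
            snorna_id = model$id, ase_kind = ases$kind[j],
            contig = ctg, strand = strand,
            target_start = t0, target_end = t0 + L,
            n_pairs = d$n_pairs, n_gu_pairs = d$n_gu,
            n_mismatches = d$n_mismatches, duplex_score = d$score,
            predicted_nm_pos = pred, site_pos = pos,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(snorna_id = character(0), ase_kind = character(0),
                      contig = character(0), strand = character(0),
                      target_start = integer(0), target_end = integer(0),
                      n_pairs = integer(0), n_gu_pairs = integer(0),
                      n_mismatches = integer(0), duplex_score = integer(0),
                      predicted_nm_pos = integer(0), site_pos = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$duplex_score, res$snorna_id, res$site_pos), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.pair_score_lookup <- local({
  sc <- c(AU = 2L, UA = 2L, GC = 2L, CG = 2L, GU = 1L, UG = 1L)
  function(pair) {
    s <- sc[pair]
    s[is.na(s)] <- -2L
    unname(s)
  }
})

#' Best duplex score between snoRNAs and Nm-site windows
#'
#' For each (snoRNA, site) pair, finds the maximum additive duplex score
#' over all ungapped antiparallel placements of any snoRNA subsequence of
#' at least `min_len` nt against the site's +/- `window` nt region, with
#' no canonical-offset requirement. Supports ranking snoRNAs (e.g. the
#' abundant U3/U8/U13 species) by complementarity to each site.
#'
#' @inheritParams scan_targets
#' @param min_len minimum duplex length considered (nt).
#' @return data.frame snorna_id, contig, pos, strand, best_score
#'   (NA when the window contains N or lies outside the contig).
#' @export
mfe_windows <- function(snornas, nm_sites, reference, window = 7L,
                        min_len = 8L) {
  rows <- list()
  for (i in seq_len(nrow(nm_sites))) {
    ctg <- nm_sites$contig[i]; pos <- nm_sites$pos[i]
    strand <- nm_sites$strand[i]
    Lc <- contig_length(reference, ctg)
    ok <- pos - window >= 0L && pos + window + 1L <= Lc
    wseq <- NULL
    if (ok) {
      win <- contig_window(reference, ctg, pos - window, pos + window + 1L)
      if (!grepl("N", win, fixed = TRUE))
        wseq <- strsplit(if (strand == "+") to_rna(win) else revcomp_rna(win),
                         "", fixed = TRUE)[[1]]
    }
    for (model in snornas) {
      best <- NA_integer_
      if (!is.null(wseq)) best <- best_duplex_score(model$seq, wseq, min_len)
      rows[[length(rows) + 1L]] <- data.frame(
        snorna_id = model$id, contig = ctg, pos = pos, strand = strand,
        best_score = best, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Maximum-scoring ungapped antiparallel duplex of length >= min_len
# between any subsequence of sno_seq and the window (already split into
# characters, transcript orientation). Pairs lie on anti-diagonals of the
# (snoRNA index + window index) grid, so each diagonal is scanned for its
# best contiguous run.
best_duplex_score <- function(sno_seq, wseq, min_len) {
  s <- strsplit(to_rna(sno_seq), "", fixed = TRUE)[[1]]
  M <- length(s); W <- length(wseq)
  if (min_len > min(M, W)) return(NA_integer_)
  best <- NA_integer_
  for (d in (min_len - 1L):(M + W - 1L - min_len)) {
    i <- max(0L, d - W + 1L):min(M - 1L, d)
    j <- d - i
    v <- .pair_score_lookup(paste0(s[i + 1L], wseq[j + 1L]))
    n <- length(v)
    if (n < min_len) next
    cs <- c(0L, cumsum(v))
    for (len in min_len:n) {
      seg <- cs[(len + 1L):(n + 1L)] - cs[1L:(n - len + 1L)]
      m <- max(seg)
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}
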