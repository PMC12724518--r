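test_that("box motifs are found and assigned canonically", {
  # C at offset 0 (R = A), one internal D' candidate, D at the 3'-most CUGA
  seq <- paste0("AUGAUGA", "CCAAUUCCAAUU", "CUGA", "CCAAUUCCAAUUCC", "CUGA",
                "CCAAUU")
  boxes <- find_boxes(seq)
  expect_identical(boxes$start[boxes$kind == "C"], 0L)
  expect_identical(boxes$start[boxes$kind == "D"], 37L)
  expect_identical(boxes$start[boxes$kind == "Dprime"], 19L)

  nb <- find_boxes(strrep("A", 30))
  expect_identical(nrow(nb), 0L)
  expect_match(attr(nb, "diagnostic"), "box")
})

test_that("ASE extraction respects box offsets and the 10 nt minimum", {
  seq <- paste0(strrep("A", 48), "CCCCCCCCCCCC", "CUGA", "CC")
  m <- structure(list(id = "x", seq = seq,
                      boxes = data.frame(kind = c("C", "D"),
                                         start = c(0L, 60L),
                                         seq = c("AUGAUGA", "CUGA"))),
                 class = "snorna_model")
  m <- extract_ases(m, ase_length = 12L)
  expect_identical(m$ases$start, 48L)
  expect_identical(m$ases$end, 60L)

  short <- structure(list(id = "y", seq = paste0(strrep("G", 8), "CUGA",
                                                 strrep("A", 20)),
                          boxes = data.frame(kind = "D", start = 8L,
                                             seq = "CUGA")),
                     class = "snorna_model")
  short <- extract_ases(short)
  expect_identical(nrow(short$ases), 0L)
})

test_that("duplex scoring matches hand counts", {
  x <- "ACGUACGUACGU"
  d <- duplex_score(x, revcomp_rna(x))
  expect_identical(d$n_pairs, 12L)
  expect_identical(d$score, 24L)

  # one central mismatch: flip the base pairing with ASE offset 5
  t <- strsplit(revcomp_rna(x), "")[[1]]
  t[12 - 5] <- "C"  # partner of ASE offset 5 ("C"); C:C is a mismatch
  d2 <- duplex_score(x, paste(t, collapse = ""))
  expect_identical(d2$n_pairs, 11L)
  expect_identical(d2$n_mismatches, 1L)
  expect_identical(d2$score, 20L)

  # all-mismatch window
  d3 <- duplex_score("AAAAAAAAAAAA", "CCCCCCCCCCCC")
  expect_identical(d3$score, -24L)
  # G:U wobble scores +1
  expect_identical(duplex_score("G", "A")$score, -2L)
  expect_identical(duplex_score("G", "U")$score, 1L)
  expect_error(duplex_score("ACGU", "ACG"), "equal length")
})

test_that("duplex of any sequence with its reverse complement is perfect", {
  withr::with_seed(42, {
    for (i in 1:20) {
      L <- sample(8:20, 1)
      x <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                 collapse = "")
      d <- duplex_score(x, revcomp_rna(x))
      expect_identical(d$score, 2L * L)
      expect_identical(d$n_mismatches, 0L)
    }
  })
})

test_that("the D+5 rule maps window indices as derived", {
  # ASE of length 12 ending at box D start 60, window starting at 1000:
  # snoRNA offset 59 pairs 1000, so offset 55 pairs 1004
  expect_identical(predict_nm_position(48L, 60L, 1000L, 12L, "+"), 1004L)
  expect_identical(predict_nm_position(48L, 60L, 1000L, 12L, "-"), 1007L)
  # pairing not covering d-5 (ASE too short)
  expect_true(is.na(predict_nm_position(57L, 60L, 1000L, 3L, "+")))
})

test_that("scan rejects high-scoring duplexes at non-canonical offsets", {
  ref <- build_reference(c(chr1 = 10000L), seed = 6)
  sno <- design_snornas(ref, data.frame(contig = "chr1", pos = 5000L,
                                        strand = "+"))[[1]]
  # the duplex is perfect at 5000; the same snoRNA must not match a site
  # reported 4 nt away even though the duplex score there is unchanged
  hits <- scan_targets(list(sno), data.frame(contig = "chr1", pos = 5004L,
                                             strand = "+"), ref)
  expect_false(any(hits$n_mismatches == 0L & hits$duplex_score == 24L))
})

test_that("scan is symmetric under a strand flip of the reference", {
  ref <- build_reference(c(chr1 = 4000L), n_transcripts = 2L, seed = 7)
  pos <- 2000L
  sno <- design_snornas(ref, data.frame(contig = "chr1", pos = pos,
                                        strand = "+"))
  L <- length(ref$contigs[[1]])
  mirrored <- ref
  mirrored$contigs <- Biostrings::reverseComplement(ref$contigs)
  names(mirrored$contigs) <- names(ref$contigs)
  hits_f <- scan_targets(sno, data.frame(contig = "chr1", pos = pos,
                                         strand = "+"), ref)
  hits_r <- scan_targets(sno, data.frame(contig = "chr1",
                                         pos = L - 1L - pos,
                                         strand = "-"), mirrored)
  expect_identical(nrow(hits_f), nrow(hits_r))
  expect_identical(hits_f$duplex_score, hits_r$duplex_score)
  expect_identical(L - 1L - hits_f$predicted_nm_pos,
                   hits_r$predicted_nm_pos)
})

test_that("design/box/ASE/prediction round-trips for many random designs", {
  ref <- build_reference(c(chr1 = 30000L), n_transcripts = 10L, seed = 8)
  pos <- choose_site_positions(ref, 40, seed = 9)
  snos <- design_snornas(ref, pos, guide_length = 12L)
  hits <- scan_targets(snos, pos, ref)
  for (i in seq_len(nrow(pos))) {
    h <- hits[hits$snorna_id == snos[[i]]$id & hits$site_pos == pos$pos[i], ]
    expect_gte(nrow(h), 1L)
    expect_true(any(h$n_mismatches == 0L & h$predicted_nm_pos == pos$pos[i]))
  }
})

test_that("best-window duplex scores match an exhaustive oracle", {
  brute <- function(sno, win, min_len = 8L) {
    s <- strsplit(to_rna(sno), "")[[1]]; w <- strsplit(to_rna(win), "")[[1]]
    sc <- function(a, b) {
      p <- paste0(a, b)
      if (p %in% c("AU", "UA", "GC", "CG")) 2L
      else if (p %in% c("GU", "UG")) 1L else -2L
    }
    best <- NA_integer_
    for (o in min_len:min(length(s), length(w)))
      for (i in 0:(length(s) - o)) for (j in 0:(length(w) - o)) {
        tot <- sum(vapply(0:(o - 1L), function(k)
          sc(s[i + k + 1L], w[j + o - k]), integer(1)))
        if (is.na(best) || tot > best) best <- tot
      }
    best
  }
  withr::with_seed(10, {
    ref <- build_reference(c(chr1 = 2000L), n_transcripts = 1L, seed = 11)
    for (i in 1:20) {
      sno <- snorna_model("z", paste0(
        "UUCCAUUAUGAUGA",
        paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
              collapse = ""), "CUGACCAAUU"))
      site <- data.frame(contig = "chr1",
                         pos = sample(500:1500, 1), strand = "+")
      got <- mfe_windows(list(sno), site, ref)$best_score
      win <- substring(as.character(ref$contigs[[1]]), site$pos - 6,
                       site$pos + 8)
      expect_identical(got, brute(sno$seq, to_rna(win)))
    }
  })
})

test_that("a window matching the reverse complement of a snoRNA stretch ranks first", {
  ref <- build_reference(c(chr1 = 2000L), n_transcripts = 1L, seed = 12)
  site <- data.frame(contig = "chr1", pos = 1000L, strand = "+")
  win <- to_rna(substring(as.character(ref$contigs[[1]]), 994, 1008))
  planted <- snorna_model("match", paste0("UUCCAUUAUGAUGACCAUU",
                                          revcomp_rna(win),
                                          "CCAUUCUGACCAAUU"))
  withr::with_seed(13, decoys <- lapply(1:5, function(i)
    snorna_model(paste0("rand", i), paste0(
      "UUCCAUUAUGAUGA",
      paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
            collapse = ""), "CUGACCAAUU"))))
  tab <- mfe_windows(c(list(planted), decoys), site, ref)
  expect_identical(tab$snorna_id[which.max(tab$best_score)], "match")
  expect_identical(max(tab$best_score), 30L)
})
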