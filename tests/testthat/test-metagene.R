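test_that("GTF annotation round-trips through write_reference", {
  ref <- build_reference(c(chr1 = 6000L), n_transcripts = 3L, seed = 60)
  tmp <- withr::local_tempdir()
  write_reference(ref, file.path(tmp, "r.fa"), file.path(tmp, "r.gtf"))
  models <- load_annotation(file.path(tmp, "r.gtf"))
  expect_length(models, 3L)
  tx <- ref$transcripts
  for (m in models) {
    i <- match(m$id, tx$transcript_id)
    expect_identical(m$exons$start, tx$start[i])
    expect_identical(m$exons$end, tx$end[i])
    expect_identical(m$cds, c(tx$cds_start[i], tx$cds_end[i]))
    expect_identical(m$strand, tx$strand[i])
  }
})

test_that("a CDS outside the exons is skipped with a warning", {
  tmp <- withr::local_tempdir()
  gtf <- file.path(tmp, "bad.gtf")
  writeLines(c(
    'c1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\tCDS\t301\t400\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t501\t700\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  expect_warning(models <- load_annotation(gtf), "CDS outside exons")
  expect_length(models, 1L)
  expect_identical(models[[1]]$id, "t2")
})

# hand-built transcripts: plus strand with two exons, minus strand, and a
# noncoding transcript
toy_models <- function() {
  structure(list(
    list(id = "plus", contig = "c1", strand = "+",
         exons = data.frame(start = c(100L, 300L), end = c(200L, 400L)),
         cds = c(150L, 350L)),
    list(id = "minus", contig = "c1", strand = "-",
         exons = data.frame(start = 1000L, end = 1200L),
         cds = c(1050L, 1150L)),
    list(id = "nc", contig = "c1", strand = "+",
         exons = data.frame(start = 2000L, end = 2100L), cds = NULL)),
    class = "transcript_models")
}

test_that("region assignment is strand-aware across half-open boundaries", {
  m <- toy_models()
  site <- function(pos, strand = "+")
    data.frame(contig = "c1", pos = pos, strand = strand)
  expect_identical(assign_region(site(149L), m)$region, "5UTR")
  expect_identical(assign_region(site(150L), m)$region, "CDS")
  # CDS spans the intron: transcript position picks up after the gap
  expect_identical(assign_region(site(300L), m)$region, "CDS")
  expect_identical(assign_region(site(350L), m)$region, "3UTR")
  expect_identical(assign_region(site(399L), m)$region, "3UTR")
  expect_identical(assign_region(site(400L), m)$region, "unassigned")
  expect_identical(assign_region(site(250L), m)$region, "unassigned")
  # minus strand: the genomically rightmost segment is the 5'UTR
  expect_identical(assign_region(site(1180L, "-"), m)$region, "5UTR")
  expect_identical(assign_region(site(1100L, "-"), m)$region, "CDS")
  expect_identical(assign_region(site(1010L, "-"), m)$region, "3UTR")
  # opposite strand of an exon is not assigned
  expect_identical(assign_region(site(1100L, "+"), m)$region, "unassigned")
  expect_identical(assign_region(site(2050L), m)$region, "noncoding_exon")
  # metagene coordinate lands in the region's unit interval
  expect_true(assign_region(site(350L), m)$metagene_coord >= 2)
})

test_that("region assignment mirrors exactly under genome reflection", {
  ref <- build_reference(c(chr1 = 6000L), n_transcripts = 2L, seed = 61)
  models <- as_transcript_models(ref)
  L <- 6000L
  mirrored <- structure(lapply(models, function(m) {
    m2 <- m
    m2$strand <- if (m$strand == "+") "-" else "+"
    m2$exons <- data.frame(start = L - rev(m$exons$end),
                           end = L - rev(m$exons$start))
    m2$cds <- c(L - m$cds[2L], L - m$cds[1L])
    m2
  }), class = "transcript_models")
  sites <- choose_site_positions(ref, 10, seed = 62)
  a <- assign_region(sites, models)
  msites <- sites
  msites$pos <- L - 1L - sites$pos
  msites$strand <- ifelse(sites$strand == "+", "-", "+")
  b <- assign_region(msites, mirrored)
  expect_identical(a$region, b$region)
  expect_equal(a$metagene_coord, b$metagene_coord)
})

test_that("a planted 5/55/40 split is recovered exactly", {
  ref <- build_reference(c(chr1 = 30000L), n_transcripts = 3L,
                         proportions = c(0.05, 0.55, 0.40), seed = 63)
  models <- as_transcript_models(ref)
  tx <- ref$transcripts[1, ]  # plus-strand transcript
  seg <- c(tx$cds_start - tx$start, tx$cds_end - tx$cds_start,
           tx$end - tx$cds_end)
  pick <- function(lo, n) lo + seq_len(n) - 1L
  pos <- c(pick(tx$start, 5L),            # 5'UTR
           pick(tx$cds_start, 55L),       # CDS
           pick(tx$cds_end, 40L))         # 3'UTR
  sites <- data.frame(contig = "chr1", pos = pos, strand = "+")
  got <- metagene_summary(assign_region(sites, models))
  expect_identical(unname(got$proportions), c(0.05, 0.55, 0.40))
  expect_identical(sum(got$density$count), 100L)
  # unassigned sites stay out of the denominator
  sites2 <- rbind(sites, data.frame(contig = "chr1", pos = 29999L,
                                    strand = "+"))
  got2 <- metagene_summary(assign_region(sites2, models))
  expect_identical(unname(got2$proportions), c(0.05, 0.55, 0.40))
  expect_identical(got2$n_unassigned, 1L)
})

test_that("CLASH intersection is half-open and matches a quadratic oracle", {
  frag <- data.frame(contig = "c1", start = 90L, end = 110L,
                     snorna_id = "U3", stringsAsFactors = FALSE)
  hit <- intersect_clash(data.frame(contig = "c1", pos = 100L, strand = "+"),
                         frag)
  expect_identical(nrow(hit), 1L)
  miss <- intersect_clash(data.frame(contig = "c1", pos = 110L,
                                     strand = "+"), frag)
  expect_identical(nrow(miss), 0L)

  withr::with_seed(64, {
    sites <- data.frame(contig = sample(c("c1", "c2"), 1000, replace = TRUE),
                        pos = sample(0:3000, 1000, replace = TRUE),
                        strand = sample(c("+", "-"), 1000, replace = TRUE))
    st <- sample(0:2950, 1000, replace = TRUE)
    frags <- data.frame(contig = sample(c("c1", "c2"), 1000, replace = TRUE),
                        start = st, end = st + sample(5:50, 1000,
                                                      replace = TRUE),
                        snorna_id = "U3", stringsAsFactors = FALSE)
  })
  got <- nrow(intersect_clash(sites, frags))
  oracle <- 0L
  for (i in seq_len(nrow(sites)))
    for (j in seq_len(nrow(frags)))
      if (sites$contig[i] == frags$contig[j] &&
          sites$pos[i] >= frags$start[j] && sites$pos[i] < frags$end[j])
        oracle <- oracle + 1L
  expect_identical(got, oracle)
})

test_that("malformed chimera BED lines are reported by line number", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t10\t20\tU3", "c1\t30\tx\tU3"), tmp)
  expect_error(intersect_clash(data.frame(contig = "c1", pos = 1L,
                                          strand = "+"), tmp),
               "line 2")
})
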