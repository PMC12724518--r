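test_that("the quality filter applies strict thresholds", {
  recs <- rbind(make_records(end3 = 1L, read_length = 20L, mean_quality = 30),
                make_records(end3 = 2L, read_length = 21L, mean_quality = 21),
                make_records(end3 = 3L, read_length = 50L, mean_quality = 20),
                make_records(end3 = 4L, read_length = 50L, mean_quality = 20.5))
  kept <- filter_records(recs)
  expect_identical(kept$end3, c(2L, 4L))
  expect_identical(nrow(filter_records(recs[0, ])), 0L)
})

test_that("UMI deduplication keeps one record per key, first wins", {
  r <- rbind(make_records(umi = "AAAAAAAAAA", mean_quality = 31),
             make_records(umi = "AAAAAAAAAA", mean_quality = 32),
             make_records(umi = "AAAAAAAAAA", mean_quality = 33),
             make_records(umi = "AAAAAAAAAC"))
  d <- dedupe_umis(r)
  expect_identical(nrow(d), 2L)
  expect_identical(d$mean_quality[1], 31)  # first occurrence retained
  # idempotence
  expect_identical(dedupe_umis(d), d)
})

test_that("deduplication agrees with a set-based oracle on random records", {
  withr::with_seed(40, {
    n <- 10000L
    recs <- data.frame(
      contig = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      end3 = sample(1:50, n, replace = TRUE),
      umi = sample(random_umis(40, 10), n, replace = TRUE),
      read_length = 50L, mean_quality = 30,
      stringsAsFactors = FALSE)
  })
  oracle <- length(unique(paste(recs$contig, recs$strand, recs$end3,
                                recs$umi, sep = "\r")))
  expect_identical(nrow(dedupe_umis(recs)), oracle)
})

test_that("coverage counts partition by strand and conserve records", {
  recs <- rbind(make_records(end3 = rep(100L, 5)),
                make_records(end3 = 100L, strand = "-", umi = "GGGGGGGGGG"))
  cov <- end3_coverage(recs)
  cc <- cov$counts
  expect_identical(cc$count[cc$strand == "+" & cc$pos == 100L], 5L)
  expect_identical(cc$count[cc$strand == "-" & cc$pos == 100L], 1L)
  expect_identical(cov$library_size, nrow(recs))
  expect_identical(sum(cc$count), cov$library_size)
})

test_that("Nm scores normalize counts per 20 million deduplicated reads", {
  cov <- structure(list(counts = data.frame(contig = "c1", strand = "+",
                                            pos = 10L, count = 100L,
                                            stringsAsFactors = FALSE),
                        library_size = 2000000L), class = "end_coverage")
  expect_identical(nm_score(cov, "c1", 10L, "+"), 1000)
  expect_identical(nm_score(cov, "c1", 11L, "+"), 0)  # absent position
  # scale invariance
  cov2 <- cov; cov2$counts$count <- 200L; cov2$library_size <- 4000000L
  expect_identical(nm_score(cov2, "c1", 10L, "+"), 1000)
  cov0 <- cov; cov0$library_size <- 0L
  expect_error(nm_score(cov0, "c1", 10L, "+"), "library size")
})

test_that("site calling combines the score threshold with local enrichment", {
  lib <- 2000000L
  mk_cov <- function(counts_df)
    structure(list(counts = counts_df, library_size = lib),
              class = "end_coverage")
  # isolated spike with empty flanks: called
  cov <- mk_cov(data.frame(contig = "c1", strand = "+", pos = 500L,
                           count = 200L, stringsAsFactors = FALSE))
  called <- call_sites(cov)
  expect_identical(called$pos, 500L)
  expect_identical(called$nm_score, 2000)
  # score 499.9 sits below the default threshold
  cov2 <- mk_cov(data.frame(contig = "c1", strand = "+", pos = 500L,
                            count = 49L, stringsAsFactors = FALSE))
  expect_identical(nrow(call_sites(cov2)), 0L)
  # uniform plateau: enrichment 1 < 10, nothing called
  cov3 <- mk_cov(data.frame(contig = "c1", strand = "+", pos = 400:600,
                            count = 100L, stringsAsFactors = FALSE))
  expect_identical(nrow(call_sites(cov3)), 0L)
  # spike below 10x the flank median: not called
  cov4 <- mk_cov(data.frame(contig = "c1", strand = "+", pos = 400:600,
                            count = c(rep(20L, 100), 150L, rep(20L, 100)),
                            stringsAsFactors = FALSE))
  expect_identical(nrow(call_sites(cov4)), 0L)
})

test_that("site calling is invariant to record input order", {
  recs <- study_records()[["CT2"]]
  base <- call_sites(end3_coverage(dedupe_umis(filter_records(recs))))
  withr::with_seed(41, shuffled <- recs[sample.int(nrow(recs)), ])
  again <- call_sites(end3_coverage(dedupe_umis(filter_records(shuffled))))
  expect_identical(base[, c("contig", "pos", "strand", "dedup_count")],
                   again[, c("contig", "pos", "strand", "dedup_count")])
})

test_that("top_k ranks by score with deterministic coordinate tie-breaks", {
  sites <- data.frame(contig = "c1", pos = c(5L, 1L, 3L, 9L),
                      strand = "+", dedup_count = 1L,
                      nm_score = c(800, 700, 700, 600),
                      sample = NA_character_, stringsAsFactors = FALSE)
  expect_identical(top_k(sites, 1L)$pos, 5L)
  got <- top_k(sites, 2L)
  expect_identical(got$pos, c(5L, 1L))  # tie at rank 2 resolved by coord
  expect_gte(min(got$nm_score), max(sites$nm_score[-match(got$pos, sites$pos)]))
  expect_warning(all4 <- top_k(sites, 10L), "exceeds")
  expect_identical(nrow(all4), 4L)
})
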