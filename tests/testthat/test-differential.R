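mk_lists <- function(score_rows) {
  # score_rows: data.frame(pos, CT2, `CT2-smDEL`, H9, `H9-smDEL`)
  conds <- c("CT2", "CT2-smDEL", "H9", "H9-smDEL")
  out <- lapply(conds, function(cd)
    data.frame(contig = "c1", pos = score_rows$pos, strand = "+",
               nm_score = score_rows[[cd]], stringsAsFactors = FALSE))
  names(out) <- conds
  out
}

test_that("presence states follow the score thresholds", {
  rows <- data.frame(pos = 1:3,
                     CT2 = c(1200, 200, 20), `CT2-smDEL` = c(0, 600, 10),
                     H9 = c(900, 700, 30), `H9-smDEL` = c(0, 800, 0),
                     check.names = FALSE)
  pm <- build_matrix(mk_lists(rows))
  expect_identical(unname(pm$states[pm$sites$pos == 1L, ]),
                   c("present", "absent", "present", "absent"))
  expect_identical(unname(pm$states[pm$sites$pos == 2L, "CT2"]), "ambiguous")
  # row 3 has no present cell and is excluded
  expect_false(3L %in% pm$sites$pos)
})

test_that("positions missing from one condition's table score 0 there", {
  conds <- c("CT2", "CT2-smDEL", "H9", "H9-smDEL")
  lists <- stats::setNames(list(
    data.frame(contig = "c1", pos = 7L, strand = "+", nm_score = 900),
    data.frame(contig = character(0), pos = integer(0),
               strand = character(0), nm_score = numeric(0)),
    data.frame(contig = "c1", pos = 7L, strand = "+", nm_score = 800),
    data.frame(contig = character(0), pos = integer(0),
               strand = character(0), nm_score = numeric(0))), conds)
  pm <- build_matrix(lists)
  expect_identical(unname(pm$scores[1, "CT2-smDEL"]), 0)
  expect_identical(unname(pm$states[1, ]),
                   c("present", "absent", "present", "absent"))
})

test_that("duplicate condition labels are rejected", {
  lists <- mk_lists(data.frame(pos = 1L, CT2 = 600, `CT2-smDEL` = 600,
                               H9 = 600, `H9-smDEL` = 600,
                               check.names = FALSE))
  names(lists)[2] <- "CT2"
  expect_error(build_matrix(lists), "duplicate")
})

test_that("presence patterns map to the documented classes", {
  P <- 1000; A <- 0; M <- 200
  rows <- data.frame(pos = 1:7,
                     CT2        = c(P, P, P, P, A, P, P),
                     `CT2-smDEL`= c(A, A, P, P, A, M, P),
                     H9         = c(A, P, P, A, P, P, P),
                     `H9-smDEL` = c(A, A, P, A, P, A, A),
                     check.names = FALSE)
  calls <- classify_sites(build_matrix(mk_lists(rows)))
  expect_identical(calls$class[match(1:7, calls$pos)],
                   c("SNORD113114_candidate", "SNORD116_candidate",
                     "shared", "CT2_specific", "H9_specific",
                     "unclassified",   # contains an ambiguous cell
                     "unclassified"))  # pattern not in the catalogue
})

test_that("classification is a pure function of the matrix", {
  rows <- data.frame(pos = c(10L, 20L, 30L),
                     CT2 = c(1000, 1000, 1000), `CT2-smDEL` = c(0, 1000, 0),
                     H9 = c(0, 1000, 1000), `H9-smDEL` = c(0, 1000, 0),
                     check.names = FALSE)
  pm <- build_matrix(mk_lists(rows))
  calls <- classify_sites(pm)
  pm_rev <- pm
  ord <- rev(seq_len(nrow(pm$sites)))
  pm_rev$sites <- pm$sites[ord, ]; rownames(pm_rev$sites) <- NULL
  pm_rev$scores <- pm$scores[ord, ]; pm_rev$states <- pm$states[ord, ]
  calls_rev <- classify_sites(pm_rev)
  key <- function(d) {
    d <- d[order(d$pos), c("pos", "class")]
    rownames(d) <- NULL
    d
  }
  expect_identical(key(calls), key(calls_rev))
})

test_that("a non-canonical condition set is refused", {
  lists <- mk_lists(data.frame(pos = 1L, CT2 = 600, `CT2-smDEL` = 600,
                               H9 = 600, `H9-smDEL` = 600,
                               check.names = FALSE))
  names(lists) <- c("a", "b", "c", "d")
  expect_error(classify_sites(build_matrix(lists)), "canonical|conditions")
})

test_that("guide assignment is family-restricted and class-gated", {
  st <- default_study()
  tr <- st$truth$sites
  s116 <- tr[tr$dependency == "SNORD116", ][1, ]
  s113 <- tr[tr$dependency == "SNORD113114", ][1, ]
  calls <- data.frame(contig = c(s116$contig, s113$contig, s116$contig),
                      pos = c(s116$pos, s113$pos, s116$pos),
                      strand = c(s116$strand, s113$strand, s116$strand),
                      class = c("SNORD116_candidate",
                                "SNORD113114_candidate", "shared"),
                      stringsAsFactors = FALSE)
  out <- assign_targets(calls, st$snornas, st$reference)
  expect_identical(out$assigned_snorna[1], s116$guide_snorna)
  expect_identical(out$assigned_snorna[2], s113$guide_snorna)
  # shared sites are never assigned, even at a perfect-duplex position
  expect_true(is.na(out$assigned_snorna[3]))
  # a candidate with no family match stays labelled but unassigned
  swapped <- out[2, ]; swapped$class <- "SNORD116_candidate"
  out2 <- assign_targets(swapped, st$snornas, st$reference)
  expect_true(is.na(out2$assigned_snorna[1]))
  expect_identical(out2$class[1], "SNORD116_candidate")
})
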