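# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Default differential study: 12 kb contig, 5 transcripts, 10 constitutive
# + 4 SNORD116 + 4 SNORD113/114 sites plus one adjacent tandem pair.
default_study <- function() fixture("study", function() build_study(seed = 3))

# Aligned 3'-end records for every condition of the default study at the
# differential depth (per-position molecule rate ~30).
study_records <- function() fixture("study_records", function() {
  st <- default_study()
  cfg <- nm_sim_config(depth = 250000)
  sapply(st$truth$conditions, function(cond) {
    simulate_riboxi(st$reference, st$truth, cfg, cond,
                    seed = 100 + match(cond, st$truth$conditions))
  }, simplify = FALSE)
})

# Deduplicated coverage and called sites per condition.
study_calls <- function() fixture("study_calls", function() {
  recs <- study_records()
  covs <- lapply(recs, function(r) end3_coverage(dedupe_umis(filter_records(r))))
  sites <- mapply(function(cv, cond) call_sites(cv, sample = cond),
                  covs, names(covs), SIMPLIFY = FALSE)
  list(coverage = covs, sites = sites)
})

make_records <- function(contig = "chr1", strand = "+", end3 = 100L,
                         umi = "ACGTACGTAC", read_length = 50L,
                         mean_quality = 35) {
  data.frame(contig = contig, strand = strand, end3 = end3, umi = umi,
             read_length = read_length, mean_quality = mean_quality,
             stringsAsFactors = FALSE)
}

# Dense end profile from explicit sparse counts.
make_profile <- function(length, ends3 = integer(0), ends5 = integer(0),
                         contig = "chrP", strand = "+", replicate_id = 1L) {
  e3 <- integer(length); e5 <- integer(length)
  if (length(ends3)) e3[as.integer(names(ends3)) + 1L] <- unname(ends3)
  if (length(ends5)) e5[as.integer(names(ends5)) + 1L] <- unname(ends5)
  end_profile(contig, strand, replicate_id, ends5 = e5, ends3 = e3)
}
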