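# End-to-end pipeline: study construction, per-stage runners and a
# declarative configuration. These functions (and the thin Rscript
# wrapper in inst/scripts/nmseq.R) bind the modules together over plain
# text formats (FASTA/GTF/BED/bedGraph/TSV/JSON).

#' Build a complete synthetic study
#'
#' Convenience constructor: builds a reference, chooses positions for the
#' snoRNA-dependent sites, designs family-labelled guide snoRNAs
#' (SNORD116-*, SNORD113-*, SNORD114-*) against them and plants the
#' truth set.
#'
#' @param seed integer seed.
#' @param design a [truth_design()].
#' @param contig_lengths,n_transcripts,proportions passed to
#'   [build_reference()].
#' @param guide_length ASE length for the designed snoRNAs.
#' @return list with elements reference, snornas, truth.
#' @export
build_study <- function(seed = 1L, design = truth_design(),
                        contig_lengths = c(chr1 = 12000L),
                        n_transcripts = 5L,
                        proportions = c(0.05, 0.55, 0.40),
                        guide_length = 12L) {
  reference <- build_reference(contig_lengths = contig_lengths,
                               n_transcripts = n_transcripts,
                               proportions = proportions,
                               seed = sub_seed(seed, 11L))
  n_dep <- design$SNORD116 + design$SNORD113114
  snornas <- list()
  if (n_dep > 0L) {
    dep_pos <- choose_site_positions(reference, n_dep,
                                     min_gap = design$min_gap,
                                     margin = design$margin,
                                     seed = sub_seed(seed, 12L))
    ids <- c(sprintf("SNORD116-%d", seq_len(design$SNORD116)),
             sprintf("SNORD11%d-%d",
                     rep(3:4, length.out = design$SNORD113114),
                     seq_len(design$SNORD113114)))
    snornas <- design_snornas(reference, dep_pos, guide_length = guide_length,
                              ids = ids)
  }
  truth <- plant_truth(reference, snornas, design = design,
                       seed = sub_seed(seed, 13L))
  list(reference = reference, snornas = snornas, truth = truth)
}

#' Pipeline configuration
#'
#' Declarative configuration with every tunable parameter of the
#' pipeline. Unknown keys are rejected; the resolved configuration is
#' echoed verbatim to `<outdir>/config.yaml` by the runners.
#'
#' @param outdir output directory.
#' @param seed master seed; per-condition and per-replicate seeds are
#'   derived deterministically from it.
#' @param depth expected molecules per contig per condition (3'-end
#'   simulator).
#' @param ribometh_depth expected cleavage reads per junction.
#' @param replicates RiboMeth-style replicates per condition.
#' @param background_end_rate,trim_budget,umi_length see
#'   [nm_sim_config()].
#' @param score_threshold,enrichment_fold,flank see [call_sites()].
#' @param present_min,absent_max see [build_matrix()].
#' @param window,min_pairs,max_mismatches see [scan_targets()].
#' @param methscore_flank,denominator_mode see [methscore()].
#' @param design a [truth_design()].
#' @param contig_lengths,n_transcripts,proportions,guide_length see
#'   [build_study()].
#' @return list of class `nm_config`.
#' @export
nm_config <- function(outdir = "nmseq_out", seed = 1L,
                      depth = 250000, ribometh_depth = 1000,
                      replicates = 3L, background_end_rate = 1e-4,
                      trim_budget = 4L, umi_length = 10L,
                      score_threshold = 500, enrichment_fold = 10,
                      flank = 50L, present_min = 500, absent_max = 50,
                      window = 7L, min_pairs = 9L, max_mismatches = 2L,
                      methscore_flank = 2L,
                      denominator_mode = "mean",
                      design = truth_design(),
                      contig_lengths = c(chr1 = 12000L),
                      n_transcripts = 5L,
                      proportions = c(0.05, 0.55, 0.40),
                      guide_length = 12L) {
  cfg <- as.list(environment())
  structure(cfg, class = "nm_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys must be a subset of the [nm_config()] arguments; unknown keys are
#' rejected with an error naming them.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file.
#' @return an `nm_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path) %||% list()
  vals[names(overrides)] <- overrides
  known <- names(formals(nm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$design)) vals$design <- do.call(truth_design, vals$design)
  if (!is.null(vals$contig_lengths))
    vals$contig_lengths <- unlist(vals$contig_lengths)
  do.call(nm_config, vals)
}

log_config <- function(config) {
  dump <- config
  dump$outdir <- as.character(dump$outdir)
  yaml::write_yaml(unclass(dump), file.path(config$outdir, "config.yaml"))
}

riboxi_seed <- function(config, condition) {
  sub_seed(config$seed, 20L + match(condition, .default_conditions))
}

#' Simulate a study and write all inputs to disk
#'
#' Writes the reference FASTA and GTF, the designed snoRNA FASTA, the
#' truth TSV, one aligned 3'-end record BED per condition and one pair
#' of end-profile bedGraphs per condition and replicate, plus a
#' `manifest.json` with md5 checksums. Outputs are staged in a temporary
#' directory and moved into place only on success, so a failing run
#' leaves no partial outputs.
#'
#' @param config an [nm_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_simulate <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, mode = 2L) != 0L)
    stop("output directory not writable: ", outdir, call. = FALSE)
  stage <- file.path(outdir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage)

  study <- build_study(seed = config$seed, design = config$design,
                       contig_lengths = config$contig_lengths,
                       n_transcripts = config$n_transcripts,
                       proportions = config$proportions,
                       guide_length = config$guide_length)
  sim_cfg <- nm_sim_config(depth = config$depth,
                           background_end_rate = config$background_end_rate,
                           trim_budget = config$trim_budget,
                           umi_length = config$umi_length,
                           replicates = config$replicates)
  write_reference(study$reference, file.path(stage, "reference.fa"),
                  file.path(stage, "reference.gtf"))
  write_snorna_fasta(study$snornas, file.path(stage, "snornas.fa"))
  write_truth_tsv(study$truth, file.path(stage, "truth.tsv"))
  for (cond in study$truth$conditions) {
    recs <- simulate_riboxi(study$reference, study$truth, sim_cfg, cond,
                            seed = riboxi_seed(config, cond))
    write_records_bed(recs, file.path(stage,
                                      sprintf("records_%s.bed", cond)))
    profs <- simulate_ribometh(study$reference, study$truth,
                               depth = config$ribometh_depth,
                               replicates = config$replicates,
                               condition = cond,
                               seed = sub_seed(config$seed,
                                               40L + match(cond,
                                                 .default_conditions)))
    for (p in profs) {
      strand_tag <- if (p$strand == "+") "plus" else "minus"
      write_profile_bedgraph(p, file.path(stage,
        sprintf("profile_%s_%s_%s_rep%d", cond, p$contig, strand_tag,
                p$replicate_id)))
    }
  }
  files <- list.files(stage)
  manifest <- list(files = as.list(stats::setNames(
    unname(tools::md5sum(file.path(stage, files))), files)))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (f in list.files(stage))
    file.rename(file.path(stage, f), file.path(outdir, f))
  unlink(stage, recursive = TRUE)
  log_config(config)
  invisible(manifest)
}

#' Call Nm sites from a record BED
#'
#' Reads aligned 3'-end records, applies the quality filter, collapses
#' UMI duplicates, computes single-nucleotide 3'-end coverage and calls
#' sites. Writes per-strand coverage bedGraphs plus a sites TSV and BED.
#'
#' @param records_bed input BED (from [run_simulate()] or any aligner
#'   post-processing emitting the same columns).
#' @param reference_fasta reference FASTA used to check contig names.
#' @param out_prefix output prefix (`<prefix>.sites.tsv`,
#'   `<prefix>.sites.bed`, `<prefix>.plus/.minus.bedgraph`).
#' @param config an [nm_config()] supplying thresholds.
#' @param sample sample label recorded on the called sites.
#' @return the called sites, invisibly.
#' @export
run_call <- function(records_bed, reference_fasta, out_prefix,
                     config = nm_config(), sample = NA_character_) {
  recs <- read_records_bed(records_bed)
  reference <- read_reference(reference_fasta)
  bad <- setdiff(unique(recs$contig), names(reference$contigs))
  if (length(bad) > 0L)
    stop("contig(s) in ", records_bed, " not present in ", reference_fasta,
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(recs) == 0L)
    warning("no records in ", records_bed, "; writing empty site table")
  recs <- dedupe_umis(filter_records(recs))
  cov <- end3_coverage(recs)
  write_coverage_bedgraph(cov, out_prefix)
  sites <- if (cov$library_size == 0L) empty_sites() else
    call_sites(cov, score_threshold = config$score_threshold,
               enrichment_fold = config$enrichment_fold,
               flank = config$flank, sample = sample)
  write_sites(sites, paste0(out_prefix, ".sites.tsv"),
              paste0(out_prefix, ".sites.bed"))
  invisible(sites)
}

#' Compute MethScore tracks from simulated profiles
#'
#' Groups the profile bedGraph pairs of one condition by contig and
#' strand, computes per-replicate MethScores and writes the aggregated
#' track (mean, SD, replicate count) as TSV plus a bedGraph of mean
#' scores.
#'
#' @param profile_dir directory holding `profile_<condition>_...`
#'   bedGraph pairs from [run_simulate()].
#' @param condition condition label.
#' @param reference_fasta reference FASTA (contig lengths).
#' @param out_prefix output prefix.
#' @param config an [nm_config()].
#' @return the MethScore track, invisibly.
#' @export
run_methscore <- function(profile_dir, condition, reference_fasta,
                          out_prefix, config = nm_config()) {
  reference <- read_reference(reference_fasta)
  pat <- sprintf("^profile_%s_(.+)_(plus|minus)_rep(\\d+)\\.ends5\\.bedgraph$",
                 condition)
  files <- list.files(profile_dir, pattern = pat)
  stop_if_not(length(files) > 0L,
              paste0("no profiles for condition ", condition))
  meta <- regmatches(files, regexec(pat, files))
  tracks <- list()
  groups <- unique(vapply(meta, function(m) paste(m[2L], m[3L]), character(1)))
  for (g in groups) {
    parts <- strsplit(g, " ", fixed = TRUE)[[1L]]
    ctg <- parts[1L]; strand <- if (parts[2L] == "plus") "+" else "-"
    reps <- sort(as.integer(vapply(
      meta[vapply(meta, function(m) paste(m[2L], m[3L]), character(1)) == g],
      function(m) m[4L], character(1))))
    profiles <- lapply(reps, function(r)
      read_profile_bedgraph(file.path(profile_dir,
        sprintf("profile_%s_%s_%s_rep%d", condition, ctg, parts[2L], r)),
        ctg, strand, contig_length(reference, ctg), replicate_id = r))
    tracks[[g]] <- methscore_track(profiles, flank = config$methscore_flank,
                                   denominator_mode = config$denominator_mode)
  }
  track <- do.call(rbind, tracks)
  rownames(track) <- NULL
  utils::write.table(track, paste0(out_prefix, ".methscore.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%.4f", track$contig, track$pos,
                     track$pos + 1L, track$methscore_mean),
             paste0(out_prefix, ".methscore.bedgraph"))
  invisible(track)
}

#' Scan called sites for canonical snoRNA guides
#'
#' @param sites_tsv called-site TSV from [run_call()].
#' @param snorna_fasta snoRNA FASTA.
#' @param reference_fasta reference FASTA.
#' @param out_tsv output matches TSV.
#' @param config an [nm_config()].
#' @return the guide matches, invisibly.
#' @export
run_guide <- function(sites_tsv, snorna_fasta, reference_fasta, out_tsv,
                      config = nm_config()) {
  sites <- read_sites_tsv(sites_tsv)
  snornas <- read_snorna_fasta(snorna_fasta,
                               ase_length = config$guide_length)
  reference <- read_reference(reference_fasta)
  matches <- scan_targets(snornas, sites, reference,
                          window = config$window,
                          min_pairs = config$min_pairs,
                          max_mismatches = config$max_mismatches)
  utils::write.table(matches, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matches)
}

#' Differential classification and orphan snoRNA assignment
#'
#' Takes the per-condition called sites and coverage written by
#' [run_call()], re-scores the union of called positions in every
#' condition from its deduplicated coverage, builds the presence/absence
#' matrix, classifies each site and assigns family-restricted canonical
#' guides.
#'
#' @param call_prefixes named character vector (condition -> the
#'   `out_prefix` given to [run_call()] for that condition); names must
#'   be the four canonical conditions.
#' @param snorna_fasta,reference_fasta inputs for guide assignment.
#' @param out_prefix output prefix (`<prefix>.matrix.tsv`,
#'   `<prefix>.calls.tsv`).
#' @param config an [nm_config()].
#' @return the classified calls, invisibly.
#' @export
run_diff <- function(call_prefixes, snorna_fasta, reference_fasta,
                     out_prefix, config = nm_config()) {
  site_lists <- lapply(call_prefixes, function(p)
    read_sites_tsv(paste0(p, ".sites.tsv")))
  union_pos <- unique(do.call(rbind, lapply(site_lists, function(d)
    d[, c("contig", "pos", "strand"), drop = FALSE])))
  score_tables <- lapply(call_prefixes, function(p) {
    cov <- read_coverage_bedgraph(p)
    d <- union_pos
    d$nm_score <- score_positions(cov, union_pos)
    d
  })
  pm <- build_matrix(score_tables, present_min = config$present_min,
                     absent_max = config$absent_max)
  calls <- classify_sites(pm)
  snornas <- read_snorna_fasta(snorna_fasta,
                               ase_length = config$guide_length)
  reference <- read_reference(reference_fasta)
  calls <- assign_targets(calls, snornas, reference,
                          window = config$window,
                          min_pairs = config$min_pairs,
                          max_mismatches = config$max_mismatches)
  states <- as.data.frame(pm$states)
  names(states) <- paste0("state_", names(states))
  utils::write.table(cbind(pm$sites, as.data.frame(pm$scores), states),
                     paste0(out_prefix, ".matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(calls, paste0(out_prefix, ".calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Annotate sites with transcript regions and CLASH overlaps
#'
#' @param sites_tsv called-site TSV.
#' @param gtf_path transcript annotation (GTF or BED12).
#' @param out_prefix output prefix (`<prefix>.regions.tsv`,
#'   `<prefix>.metagene.tsv`, optionally `<prefix>.clash.tsv`).
#' @param clash_bed optional chimera-fragment BED.
#' @return list with assignments, summary and (optionally) clash
#'   overlaps, invisibly.
#' @export
run_annotate <- function(sites_tsv, gtf_path, out_prefix,
                         clash_bed = NULL) {
  sites <- read_sites_tsv(sites_tsv)
  models <- load_annotation(gtf_path)
  assignments <- assign_region(sites, models)
  summary <- metagene_summary(assignments)
  utils::write.table(assignments, paste0(out_prefix, ".regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  props <- data.frame(region = names(summary$proportions),
                      proportion = as.numeric(summary$proportions),
                      count = as.integer(summary$counts))
  utils::write.table(props, paste0(out_prefix, ".metagene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(assignments = assignments, summary = summary)
  if (!is.null(clash_bed)) {
    out$clash <- intersect_clash(sites, clash_bed)
    utils::write.table(out$clash, paste0(out_prefix, ".clash.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Run the whole pipeline
#'
#' simulate -> per-condition calling -> MethScore -> differential
#' classification with guide assignment -> annotation, all under
#' `config$outdir`.
#'
#' @param config an [nm_config()].
#' @return invisibly, a list with the called sites per condition, the
#'   classified calls and the metagene summary.
#' @export
run_all <- function(config = nm_config()) {
  run_simulate(config)
  outdir <- config$outdir
  ref_fa <- file.path(outdir, "reference.fa")
  per_cond <- list()
  prefixes <- character(0)
  for (cond in .default_conditions) {
    prefix <- file.path(outdir, paste0("call_", cond))
    per_cond[[cond]] <- run_call(file.path(outdir,
                                           sprintf("records_%s.bed", cond)),
                                 ref_fa, prefix, config, sample = cond)
    prefixes[cond] <- prefix
  }
  run_methscore(outdir, "CT2", ref_fa, file.path(outdir, "CT2"), config)
  calls <- run_diff(prefixes, file.path(outdir, "snornas.fa"), ref_fa,
                    file.path(outdir, "diff"), config)
  ann <- run_annotate(paste0(prefixes[["CT2"]], ".sites.tsv"),
                      file.path(outdir, "reference.gtf"),
                      file.path(outdir, "annotate_CT2"))
  invisible(list(sites = per_cond, calls = calls,
                 metagene = ann$summary))
}
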