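# End-to-end pipeline: simulate (or load) -> qc -> normalize -> classify,
# with a manifest of checksummed artifacts and a drop-accounting log.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. A config
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Master seed; every source of randomness derives from it.
#' @param outdir Output directory for artifacts (created if absent).
#' @param simulate Generate the screen (`TRUE`) or read `counts_path` /
#'   `plate_map_path` / `panel_path` (`FALSE`).
#' @param counts_path,plate_map_path,panel_path Input TSVs when
#'   `simulate = FALSE`.
#' @param n_chemicals Chemical slots for a simulated screen (352 fills
#'   twenty-four 384-well plates exactly at the defaults).
#' @param n_replicates,sexes,concentrations,plate_size Design parameters.
#' @param min_well_reads,min_probe_reads,strict_filters QC thresholds.
#' @param pseudocount,polish_tol,polish_max_iter,polish_output
#'   Normalization parameters.
#' @param threshold Signature-retention correlation threshold.
#' @param cluster_method Linkage for hierarchical clustering.
#' @param collapse_sexes Average the sexes before correlating/classifying
#'   (the chemical-by-concentration reporting convention).
#' @param write_fastq Also emit synthetic FASTQ (simulated runs only).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       outdir = tempfile("rasl_run_"),
                       simulate = TRUE,
                       counts_path = NULL, plate_map_path = NULL,
                       panel_path = NULL,
                       n_chemicals = 352, n_replicates = 3,
                       sexes = c("M", "F"),
                       concentrations = c(0.01, 0.1, 1, 10),
                       plate_size = 384,
                       min_well_reads = 500, min_probe_reads = 1000,
                       strict_filters = TRUE,
                       pseudocount = 1, polish_tol = 1e-6,
                       polish_max_iter = 20,
                       polish_output = "residual_plus_row",
                       threshold = 0.65, cluster_method = "average",
                       collapse_sexes = TRUE,
                       write_fastq = FALSE) {
  cfg <- as.list(environment())
  cfg$version <- as.character(utils::packageVersion("raslscreen"))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[setdiff(names(cfg), "version")]
  args <- args[names(args) %in% names(formals(run_config))]
  do.call(run_config, args)
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Default template assignment for a simulated screen
#'
#' Assigns effect templates and dose models to chemical slots the way a
#' real library behaves: named hallmark compounds get their published
#' cluster (bifenthrin-like pyrethroids C1 -- bifenthrin with a
#' 10-uM-threshold dose response; strobilurins/electron-transport
#' inhibitors C2 -- pyraclostrobin flat across concentrations,
#' azoxystrobin threshold-only; topoisomerase inhibitors C5; JQ1 novel),
#' a slice of the anonymous slots gets each remaining template, and the
#' bulk stays null (transcriptionally inactive).
#'
#' @param chemicals Chemical ids (see [default_chemicals()]).
#' @param frac_active Approximate fraction of anonymous slots carrying a
#'   non-null template.
#' @return An [effect_profiles()] object.
#' @export
demo_profiles <- function(chemicals = default_chemicals(),
                          frac_active = 0.25) {
  template <- rep("null", length(chemicals))
  dose <- rep("flat", length(chemicals))
  names(template) <- names(dose) <- chemicals
  set_if <- function(ids, tpl, dm) {
    ids <- intersect(ids, chemicals)
    template[ids] <<- tpl
    dose[ids] <<- dm
  }
  set_if(c("fenpropathrin", "esfenvalerate", "NMDA"), "C1", "flat")
  set_if("bifenthrin", "C1", "threshold")
  set_if(c("pyraclostrobin", "trifloxystrobin", "kresoxim-methyl",
           "fenamidone", "fenpyroximate", "rotenone", "diquat_dibromide",
           "fluazinam"), "C2", "flat")
  set_if("azoxystrobin", "C2", "threshold")
  set_if(c("topotecan", "camptothecin"), "C5", "monotone")
  set_if("JQ1", "novel", "flat")
  anon <- chemicals[template == "null" & startsWith(chemicals, "chem")]
  n_active <- round(length(anon) * frac_active)
  if (n_active > 0) {
    pick <- anon[seq_len(n_active)]
    tpls <- rep(c("C1", "C2", "C3", "C4", "C5", "C6"), length.out = n_active)
    dms <- rep(c("flat", "threshold", "monotone"), length.out = n_active)
    template[pick] <- tpls
    dose[pick] <- dms
  }
  effect_profiles(chemicals, template = template, dose_model = dose)
}

run_log <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Executes simulate (or load) -> QC -> normalization -> sex inference ->
#' signature correlation -> classification -> hierarchical clustering,
#' writes every artifact as TSV (plus a Newick tree and a plain-text run
#' log with per-stage drop accounting), and finishes with a manifest of
#' all outputs and their MD5 checksums. Re-running with the same config
#' reproduces byte-identical artifacts.
#'
#' @param config A [run_config()] (or path to its YAML form).
#' @return A `rasl_run` list: `config`, `manifest` (file, md5), `qc`
#'   report, normalized matrices, `sex_calls`, `correlations`,
#'   `classification`, the `hclust` tree, and (simulated runs) the ground
#'   truth -- invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  truth <- NULL
  if (isTRUE(config$simulate)) {
    panel <- default_panel(junctions = isTRUE(config$write_fastq))
    design <- make_design(default_chemicals(config$n_chemicals),
                          n_replicates = config$n_replicates,
                          sexes = config$sexes,
                          concentrations = config$concentrations,
                          plate_size = config$plate_size,
                          seed = config$seed)
    profiles <- demo_profiles(default_chemicals(config$n_chemicals))
    sim <- simulate_counts(design, panel, profiles,
                           sim_config(seed = config$seed))
    counts <- sim$counts
    truth <- sim$truth
    say("simulated screen: %d wells x %d probes on %d plates (seed %d)",
        nrow(counts), ncol(counts), length(unique(design$plate_id)),
        config$seed)
    write_probe_panel(panel, out("panel.tsv"))
    write_plate_map(design, out("plate_map.tsv"))
    write_count_matrix(counts, out("counts.tsv"))
    utils::write.table(truth$well, out("ground_truth_wells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$chemical, out("ground_truth_chemicals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$write_fastq))
      simulate_fastq(counts, design, panel, out("reads.fastq"),
                     seed = config$seed)
  } else {
    if (is.null(config$counts_path) || is.null(config$plate_map_path) ||
        is.null(config$panel_path))
      stop("usage: simulate = FALSE requires counts_path, plate_map_path and panel_path")
    panel <- read_probe_panel(config$panel_path)
    design <- read_plate_map(config$plate_map_path,
                             plate_size = config$plate_size)
    counts <- read_count_matrix(config$counts_path, panel)
    say("loaded screen: %d wells x %d probes", nrow(counts), ncol(counts))
  }

  qc <- qc_screen(counts, panel,
                  min_well_reads = config$min_well_reads,
                  min_probe_reads = config$min_probe_reads,
                  strict = config$strict_filters)
  for (w in qc$report$wells$well_id[!qc$report$wells$pass])
    say("dropped well %s: total reads %.0f <= %d", w,
        qc$report$wells$total_reads[qc$report$wells$well_id == w],
        config$min_well_reads)
  for (p in qc$report$probes$probe_id[!qc$report$probes$pass])
    say("dropped probe %s: total reads %.0f <= %d", p,
        qc$report$probes$total_reads[qc$report$probes$probe_id == p],
        config$min_probe_reads)
  say("qc: retained %d/%d wells, %d/%d probes",
      sum(qc$report$wells$pass), nrow(qc$report$wells),
      sum(qc$report$probes$pass), nrow(qc$report$probes))
  utils::write.table(qc$report$wells, out("qc_wells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qc$report$probes, out("qc_probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_count_matrix(qc$counts, out("counts_filtered.tsv"))

  norm <- normalize_screen(qc$counts, panel, design,
                           pseudocount = config$pseudocount,
                           tol = config$polish_tol,
                           max_iter = config$polish_max_iter,
                           polish_output = config$polish_output)
  for (g in attr(norm$condition, "dropped_conditions"))
    say("dropped condition %s: no surviving wells", g)
  say("normalization: %d genes x %d wells; %d chemical-concentration-sex profiles passed QC; polish converged=%s after %d sweeps",
      nrow(norm$well), ncol(norm$well), ncol(norm$condition),
      attr(norm$well, "converged"), attr(norm$well, "iterations"))
  write_norm <- function(x, f) {
    df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_norm(norm$well, "expression_well.tsv")
  write_norm(norm$condition, "expression_condition.tsv")
  write_norm(norm$centered, "expression_centered.tsv")

  sex_calls <- infer_sex(norm$condition)
  utils::write.table(sex_calls, out("sex_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  centered <- norm$centered
  if (isTRUE(config$collapse_sexes)) centered <- average_sexes(centered)
  signatures <- fixture_signatures(panel)
  corr <- correlate_to_signatures(centered, signatures)
  utils::write.table(
    data.frame(condition = rownames(corr), as.data.frame(unclass(corr)),
               check.names = FALSE),
    out("signature_correlations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  health <- tapply(qc$report$wells$spike_fraction,
                   design$chemical_id[match(qc$report$wells$well_id,
                                            design_well_ids(design))],
                   stats::median, na.rm = TRUE)
  cls <- assign_clusters(corr, threshold = config$threshold,
                         health = health)
  utils::write.table(as.data.frame(cls), out("classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("classification: %d classified, %d ambiguous, %d below threshold",
      sum(cls$status == "classified"),
      sum(cls$status == "unclassified_ambiguous"),
      sum(cls$status == "unclassified_low"))

  tree <- hierarchical_cluster(centered, method = config$cluster_method)
  writeLines(as_newick(tree), out("conditions.nwk"))
  write_norm(centered[, tree$order, drop = FALSE], "heatmap_matrix.tsv")

  run_log(log_lines, out("run.log"))
  files <- sort(list.files(config$outdir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  res <- list(config = config, manifest = manifest, qc = qc$report,
              norm = norm, sex_calls = sex_calls, correlations = corr,
              classification = cls, tree = tree, truth = truth,
              log = log_lines)
  class(res) <- "rasl_run"
  invisible(res)
}

#' @export
print.rasl_run <- function(x, ...) {
  cat("RASL screen pipeline run\n")
  cat(sprintf("  outdir: %s (%d artifacts)\n", x$config$outdir,
              nrow(x$manifest)))
  cat(sprintf("  wells retained: %d/%d; probes retained: %d/%d\n",
              sum(x$qc$wells$pass), nrow(x$qc$wells),
              sum(x$qc$probes$pass), nrow(x$qc$probes)))
  cat(sprintf("  condition profiles passing QC: %d\n",
              ncol(x$norm$condition)))
  print(x$classification)
  invisible(x)
}
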