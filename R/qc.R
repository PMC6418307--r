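# Read-count QC: well/probe filters and the spike-in cell-health metric.

#' Separate spike-in probes from the analysis matrix
#'
#' Luciferase spike-in counts are split off before any filtering or
#' normalization; they never participate in the control-gene scale.
#'
#' @param counts Wells x probes matrix.
#' @param panel A [probe_panel()].
#' @return List with `cellular` and `spike` sub-matrices.
#' @export
separate_spikes <- function(counts, panel) {
  spk <- intersect(colnames(counts), panel_probes(panel, "spike"))
  list(cellular = counts[, setdiff(colnames(counts), spk), drop = FALSE],
       spike = counts[, spk, drop = FALSE])
}

#' Filter wells on total read count
#'
#' Retains wells whose total reads exceed `min_total` (strictly, by
#' default: a well at exactly the threshold is dropped).
#'
#' @param counts Wells x probes matrix.
#' @param min_total Read threshold (default 500).
#' @param strict Use `>` (default) rather than `>=`.
#' @return List with the filtered `counts` and a `report` data frame
#'   (`well_id`, `total_reads`, `pass`). Dropping every well is reported,
#'   not an error.
#' @export
filter_wells <- function(counts, min_total = 500, strict = TRUE) {
  if (length(counts) == 0) stop("empty count matrix")
  tot <- rowSums(counts)
  pass <- if (strict) tot > min_total else tot >= min_total
  if (!any(pass)) warning("no wells pass the ", min_total, "-read filter")
  list(counts = counts[pass, , drop = FALSE],
       report = data.frame(well_id = rownames(counts), total_reads = tot,
                           pass = pass, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Filter probes on experiment-wide total read count
#'
#' Retains probes whose totals, summed across **all** wells of the input
#' (i.e. before any well filtering), exceed `min_total` strictly. A control
#' gene losing all its probes is a hard error because the control-gene
#' normalization scale would be undefined downstream.
#'
#' @param counts Wells x probes matrix (full, unfiltered wells).
#' @param panel Optional [probe_panel()]; enables the control-gene
#'   completeness check and reports gene/role in the output.
#' @param min_total Read threshold (default 1000).
#' @param strict Use `>` (default) rather than `>=`.
#' @return List with filtered `counts` and a per-probe `report` data frame.
#' @export
filter_probes <- function(counts, panel = NULL, min_total = 1000,
                          strict = TRUE) {
  if (length(counts) == 0) stop("empty count matrix")
  tot <- colSums(counts)
  pass <- if (strict) tot > min_total else tot >= min_total
  report <- data.frame(probe_id = colnames(counts), total_reads = tot,
                       pass = pass, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    report$gene <- panel_gene_of(panel)[report$probe_id]
    for (g in intersect(CONTROL_GENES, panel$gene)) {
      pg <- panel$probe_id[panel$gene == g]
      pg <- intersect(pg, colnames(counts))
      if (length(pg) && !any(pass[pg]))
        stop("control gene ", g,
             " lost all probes in the read filter; normalization impossible")
    }
  }
  list(counts = counts[, pass, drop = FALSE], report = report)
}

#' Luciferase spike-in read fraction per well
#'
#' The fraction of a well's total reads carried by spike-in probes,
#' used as a proxy for cell health: dying cells contribute fewer cellular
#' transcripts, so the fixed spike input claims a larger share of reads.
#' The display convention for heatmaps spans 0 to 0.25.
#'
#' @param counts Wells x probes matrix including spike probes.
#' @param panel A [probe_panel()] identifying at least one spike probe.
#' @return Named numeric vector of fractions in `[0, 1]`; wells with zero
#'   total reads get `NA`.
#' @export
luciferase_fraction <- function(counts, panel) {
  spk <- intersect(colnames(counts), panel_probes(panel, "spike"))
  if (length(spk) == 0)
    stop("panel identifies no spike probes in the count matrix")
  tot <- rowSums(counts)
  frac <- rowSums(counts[, spk, drop = FALSE]) / tot
  frac[tot == 0] <- NA_real_
  frac
}

#' Apply the full QC stage to a screen
#'
#' Order of operations: (1) compute per-well totals and spike fractions on
#' the complete matrix (totals include spike reads); (2) separate spike
#' probes; (3) filter cellular probes on totals summed over **all** wells;
#' (4) filter wells on their full totals. Both filters use strict
#' inequalities by default.
#'
#' @param counts Wells x probes matrix (full screen).
#' @param panel A [probe_panel()].
#' @param min_well_reads,min_probe_reads Thresholds (defaults 500 / 1000).
#' @param strict Strict (`>`) thresholds, the default.
#' @return List with the filtered cellular `counts` and a `qc_report`
#'   (per-well and per-probe tables, spike fractions, drop tallies).
#' @export
qc_screen <- function(counts, panel, min_well_reads = 500,
                      min_probe_reads = 1000, strict = TRUE) {
  validate_counts(counts, panel)
  spike_frac <- luciferase_fraction(counts, panel)
  parts <- separate_spikes(counts, panel)
  pf <- filter_probes(parts$cellular, panel, min_probe_reads, strict)
  wf <- filter_wells(counts, min_well_reads, strict)
  keep_wells <- wf$report$well_id[wf$report$pass]
  out <- pf$counts[keep_wells, , drop = FALSE]
  wells <- wf$report
  wells$spike_reads <- rowSums(parts$spike)[wells$well_id]
  wells$spike_fraction <- spike_frac[wells$well_id]
  report <- list(wells = wells, probes = pf$report,
                 n_wells_dropped = sum(!wells$pass),
                 n_probes_dropped = sum(!pf$report$pass),
                 thresholds = c(well = min_well_reads, probe = min_probe_reads),
                 strict = strict)
  class(report) <- "qc_report"
  list(counts = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d wells retained (> %d reads), %d/%d probes retained (> %d reads)\n",
              sum(x$wells$pass), nrow(x$wells), x$thresholds["well"],
              sum(x$probes$pass), nrow(x$probes), x$thresholds["probe"]))
  cat(sprintf("  median spike-in fraction: %.3f\n",
              stats::median(x$wells$spike_fraction, na.rm = TRUE)))
  invisible(x)
}
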