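# Probe panel: maps each ligation probe to a gene symbol and a role.

PANEL_ROLES <- c("target", "control", "spike", "sex_marker")
CONTROL_GENES <- c("Ascl3", "Psmd4", "Sdha", "Tbp")
SEX_MARKER_GENES <- c("Xist", "Ddx3y")
SPIKE_GENE <- "Luciferase"

#' Construct a probe panel
#'
#' A probe panel maps every probe to exactly one gene symbol and a role:
#' `target` (analysis gene), `control` (housekeeping genes whose geometric
#' mean sets the per-well normalization scale), `spike` (exogenous
#' luciferase spike-in, used as a cell-health proxy) or `sex_marker`
#' (Xist / Ddx3y).
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param gene Gene symbol per probe.
#' @param role One of `"target"`, `"control"`, `"spike"`, `"sex_marker"`
#'   per probe.
#' @param junction_seq Optional nucleotide sequence unique to each probe's
#'   ligation junction; required only for FASTQ counting
#'   ([count_fastq()]).
#' @return A `probe_panel` data frame with one row per probe.
#' @seealso [default_panel()] for the packaged 56-gene screening panel.
#' @export
probe_panel <- function(probe_id, gene, role, junction_seq = NULL) {
  probe_id <- as.character(probe_id)
  gene <- as.character(gene)
  role <- as.character(role)
  if (length(gene) != length(probe_id) || length(role) != length(probe_id))
    stop("probe_id, gene and role must have equal length")
  panel <- data.frame(probe_id = probe_id, gene = gene, role = role,
                      stringsAsFactors = FALSE)
  if (!is.null(junction_seq)) {
    if (length(junction_seq) != length(probe_id))
      stop("junction_seq must have one entry per probe")
    panel$junction_seq <- toupper(as.character(junction_seq))
  }
  class(panel) <- c("probe_panel", "data.frame")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$probe_id))
    stop("duplicate probe_id: ",
         paste(unique(panel$probe_id[duplicated(panel$probe_id)]), collapse = ", "))
  bad <- setdiff(unique(panel$role), PANEL_ROLES)
  if (length(bad))
    stop("unknown probe role(s): ", paste(bad, collapse = ", "))
  # one gene per probe is structural; check a gene never carries two roles
  gr <- unique(panel[, c("gene", "role")])
  if (anyDuplicated(gr$gene))
    stop("gene mapped to more than one role: ",
         paste(unique(gr$gene[duplicated(gr$gene)]), collapse = ", "))
  np <- table(panel$gene[panel$role != "spike"])
  if (any(np > 7))
    stop("genes with more than 7 probes: ",
         paste(names(np)[np > 7], collapse = ", "))
  if ("junction_seq" %in% names(panel)) {
    js <- panel$junction_seq[!is.na(panel$junction_seq)]
    if (anyDuplicated(js))
      stop("duplicate junction_seq in panel")
  }
  invisible(panel)
}

panel_probes <- function(panel, roles) {
  panel$probe_id[panel$role %in% roles]
}

panel_gene_of <- function(panel) {
  stats::setNames(panel$gene, panel$probe_id)
}

#' The packaged 56-gene neuronal screening panel
#'
#' A synthetic reconstruction of a targeted neuronal panel: 56 genes probed
#' by 261 probes (3--7 probes per gene), spanning immediate early genes,
#' oxidative-stress response, neuroinflammation/glial markers, cytoskeletal
#' genes, synaptic genes, four control (housekeeping) genes (Ascl3, Psmd4,
#' Sdha, Tbp), the sex markers Xist and Ddx3y, plus luciferase spike-in
#' probes. Gene symbols beyond those the assay is known to include are
#' plausible placeholders; the panel is a fixture for simulation and
#' testing, not a reconstruction of proprietary probe sequences.
#'
#' @param junctions If `TRUE`, attach a unique synthetic 20-nt junction
#'   sequence to every probe so the panel can be used with
#'   [simulate_fastq()] / [count_fastq()].
#' @param n_spike_probes Number of luciferase spike-in probes (not counted
#'   among the 261 gene probes).
#' @return A [probe_panel()].
#' @export
default_panel <- function(junctions = FALSE, n_spike_probes = 3) {
  targets <- c(
    # immediate early / activity-dependent
    "Fos", "Egr1", "Arc", "Npas4", "Junb", "Fosb", "Vgf", "Bdnf", "Homer1",
    # oxidative stress response
    "Hmox1", "Gsta4", "Nqo1", "Sod2", "Nfe2l2", "Casp3",
    # neuroinflammation / glial
    "Cx3cr1", "Trem2", "Aqp4", "Gfap", "C1qa", "Tnf", "Il1b", "Ccl2", "Tlr4",
    # cytoskeleton
    "Gsn", "Pdlim2", "Mapt", "App", "Ank2",
    # synaptic / long neuronal genes
    "Nrxn1", "Nrxn3", "Nlgn1", "Cntnap2", "Syt1", "Snap25", "Syn1", "Dlg4",
    "Grin2b", "Gria1", "Rbfox3", "Scn2a", "Top2b",
    # neuronal identity / regulation
    "Gad1", "Gabra1", "Camk2a", "Mef2c", "Foxp1", "Mecp2", "Shank3", "Rest")
  stopifnot(length(targets) == 50)
  # 5x7 + 8x6 + 14x5 + 17x4 + 6x3 = 239 target probes; controls 4 each,
  # sex markers 3 each -> 239 + 16 + 6 = 261 probes over 56 genes
  n_target_probes <- rep(c(7L, 6L, 5L, 4L, 3L), times = c(5L, 8L, 14L, 17L, 6L))
  genes <- c(targets, CONTROL_GENES, SEX_MARKER_GENES)
  nprobes <- c(n_target_probes, rep(4L, 4), rep(3L, 2))
  gene_col <- rep(genes, nprobes)
  probe_id <- paste0(gene_col, "_p",
                     unlist(lapply(nprobes, seq_len), use.names = FALSE))
  role <- rep(c(rep("target", 50), rep("control", 4), rep("sex_marker", 2)),
              nprobes)
  if (n_spike_probes > 0) {
    gene_col <- c(gene_col, rep(SPIKE_GENE, n_spike_probes))
    probe_id <- c(probe_id, paste0("Luc_p", seq_len(n_spike_probes)))
    role <- c(role, rep("spike", n_spike_probes))
  }
  junc <- if (junctions) make_kmers(length(probe_id), width = 20L) else NULL
  probe_panel(probe_id, gene_col, role, junction_seq = junc)
}

#' Read / write a probe panel as TSV
#'
#' Plain tab-separated table with columns `probe_id`, `gene`, `role` and
#' optionally `junction_seq`.
#'
#' @param path File path.
#' @return `read_probe_panel()` returns a validated [probe_panel()].
#' @export
read_probe_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("probe_id", "gene", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  probe_panel(df$probe_id, df$gene, df$role,
              junction_seq = if ("junction_seq" %in% names(df)) df$junction_seq)
}

#' @param panel A [probe_panel()].
#' @rdname read_probe_panel
#' @export
write_probe_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("Probe panel: %d probes, %d genes\n",
              nrow(x), length(unique(x$gene))))
  tab <- table(x$role)
  cat(paste(sprintf("  %s: %d probes", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

# Deterministic distinct k-mers over ACGT; index scrambled by an odd
# multiplicative stride so neighbouring ids do not share long prefixes.
make_kmers <- function(n, width = 8L) {
  space <- 4^width
  if (n > space) stop("cannot make ", n, " distinct ", width, "-mers")
  bases <- c("A", "C", "G", "T")
  stride <- 40503  # odd, coprime with any power of 4
  idx <- (as.double(seq_len(n) - 1) * stride) %% space
  vapply(idx, function(i) {
    d <- integer(width)
    for (k in seq_len(width)) {
      d[k] <- i %% 4
      i <- i %/% 4
    }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}
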