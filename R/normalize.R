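# Normalization chain: pseudocount -> control-gene geometric-mean log2
# ratio -> probe collapse -> Tukey median polish -> replicate collapse ->
# median centering.

new_normalized_matrix <- function(x, stage, level) {
  stopifnot(is.matrix(x), stage %in% c("well", "condition", "centered"),
            level %in% c("probe", "gene"))
  attr(x, "stage") <- stage
  attr(x, "level") <- level
  class(x) <- c("normalized_matrix", class(matrix()))
  x
}

norm_stage <- function(x) attr(x, "stage")
norm_level <- function(x) attr(x, "level")

#' Control-gene log-ratio normalization
#'
#' Adds a pseudocount to every count, then expresses each probe in a well
#' as the log2 ratio to the geometric mean of that well's control-gene
#' probes (computed in log space for stability). The mean of the
#' control-probe rows of every column is exactly zero by construction,
#' which also makes the values invariant to per-well library size.
#'
#' @param counts Wells x probes matrix (post-QC, spike probes removed).
#' @param panel A [probe_panel()]; all four control genes must retain at
#'   least one probe in `counts`.
#' @param pseudocount Added to all counts before the ratio (default 1).
#' @return Probe-level `normalized_matrix` (probes x wells, stage
#'   `"well"`).
#' @export
log_ratio_normalize <- function(counts, panel, pseudocount = 1) {
  ctrl <- intersect(colnames(counts), panel_probes(panel, "control"))
  ctrl_genes <- unique(panel_gene_of(panel)[ctrl])
  miss <- setdiff(intersect(CONTROL_GENES, panel$gene), ctrl_genes)
  if (length(miss))
    stop("control gene(s) with no probes in the matrix: ",
         paste(miss, collapse = ", "))
  if (length(ctrl) == 0) stop("no control probes in the matrix")
  lx <- log2(t(counts) + pseudocount)        # probes x wells
  geo <- colMeans(lx[ctrl, , drop = FALSE])  # log2 geometric mean per well
  v <- sweep(lx, 2, geo)
  new_normalized_matrix(v, stage = "well", level = "probe")
}

#' Collapse probes to gene level by median
#'
#' One row per gene: the per-well median over the gene's surviving probes.
#' Genes with no surviving probes are absent from the output and returned
#' in the `dropped_genes` attribute.
#'
#' @param norm Probe-level `normalized_matrix`.
#' @param panel A [probe_panel()] covering all rows.
#' @return Gene-level `normalized_matrix` (genes x wells).
#' @export
collapse_probes <- function(norm, panel) {
  stopifnot(norm_level(norm) == "probe")
  gene_of <- panel_gene_of(panel)
  miss <- setdiff(rownames(norm), names(gene_of))
  if (length(miss))
    stop("probes absent from panel: ", paste(miss, collapse = ", "))
  g <- gene_of[rownames(norm)]
  genes <- unique(panel$gene[panel$role != "spike"])
  present <- intersect(genes, g)
  out <- matrix(NA_real_, nrow = length(present), ncol = ncol(norm),
                dimnames = list(present, colnames(norm)))
  for (gn in present) {
    rows <- which(g == gn)
    out[gn, ] <- if (length(rows) == 1L) norm[rows, ]
                 else apply(norm[rows, , drop = FALSE], 2, stats::median)
  }
  res <- new_normalized_matrix(out, stage = norm_stage(norm), level = "gene")
  attr(res, "dropped_genes") <- setdiff(genes, present)
  res
}

#' Tukey two-way median polish
#'
#' Alternately sweeps row then column medians out of a gene x sample
#' matrix (rows first, Tukey's classical ordering) until the largest
#' absolute change in the residuals falls below `tol` or `max_iter` sweeps
#' have run. By default the returned values are the residuals **plus the
#' per-gene (row) effects** -- sample/column effects and the overall
#' effect are removed while gene-relative structure is preserved; set
#' `output = "residual"` for bare residuals.
#'
#' @param x Numeric matrix, >= 2 rows and >= 2 columns, all finite.
#' @param tol Convergence tolerance on the residual change (default 1e-6).
#' @param max_iter Maximum sweeps (default 20).
#' @param output `"residual_plus_row"` (default) or `"residual"`.
#' @return Matrix of the same shape with attributes `row_effects`,
#'   `col_effects`, `overall`, `iterations`, `converged`. Inherits the
#'   normalization stage/level when the input is a `normalized_matrix`.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 20,
                          output = c("residual_plus_row", "residual")) {
  output <- match.arg(output)
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value at row '%s', column '%s'",
                 rownames(x)[bad[1, 1]] %||% bad[1, 1],
                 colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  r <- unclass(x)
  row_eff <- numeric(nrow(r))
  col_eff <- numeric(ncol(r))
  overall <- 0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r_old <- r
    rd <- apply(r, 1, stats::median)
    r <- r - rd
    row_eff <- row_eff + rd
    d <- stats::median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    cd <- apply(r, 2, stats::median)
    r <- sweep(r, 2, cd)
    col_eff <- col_eff + cd
    d <- stats::median(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    if (max(abs(r - r_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  out <- if (output == "residual_plus_row") r + row_eff else r
  dimnames(out) <- dimnames(x)
  if (inherits(x, "normalized_matrix"))
    out <- new_normalized_matrix(out, norm_stage(x), norm_level(x))
  attr(out, "row_effects") <- stats::setNames(row_eff, rownames(x))
  attr(out, "col_effects") <- stats::setNames(col_eff, colnames(x))
  attr(out, "overall") <- overall
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Collapse biological replicates to condition level
#'
#' One column per chemical-concentration-sex condition: the per-gene
#' median across the condition's surviving replicate wells. Conditions
#' with no surviving wells are absent and listed in the
#' `dropped_conditions` attribute.
#'
#' @param norm Gene-level, well-stage `normalized_matrix` whose columns
#'   are well ids.
#' @param design The `plate_design` mapping wells to conditions.
#' @return Condition-level `normalized_matrix` with columns labelled
#'   `"chemical@concentration@sex"`.
#' @export
collapse_replicates <- function(norm, design) {
  wells <- design_well_ids(design)
  orphan <- setdiff(colnames(norm), wells)
  if (length(orphan))
    stop("matrix columns absent from design: ", paste(orphan, collapse = ", "))
  labels <- stats::setNames(condition_labels(design), wells)
  lab <- labels[colnames(norm)]
  conds <- unique(labels)  # design order
  present <- conds[conds %in% lab]
  out <- matrix(NA_real_, nrow = nrow(norm), ncol = length(present),
                dimnames = list(rownames(norm), present))
  for (cn in present) {
    cols <- which(lab == cn)
    out[, cn] <- if (length(cols) == 1L) norm[, cols]
                 else apply(norm[, cols, drop = FALSE], 1, stats::median)
  }
  res <- new_normalized_matrix(out, stage = "condition", level = "gene")
  attr(res, "dropped_conditions") <- setdiff(conds, present)
  res
}

#' Average the sexes of a condition-level matrix
#'
#' Collapses `"chemical@conc@M"` / `"chemical@conc@F"` column pairs to a
#' single `"chemical@conc"` column by the mean, the convention used for
#' chemical-by-concentration reporting; keep sexes separate for
#' sex-comparison views.
#'
#' @param norm Condition-level `normalized_matrix`.
#' @return `normalized_matrix` with one column per chemical-concentration.
#' @export
average_sexes <- function(norm) {
  lab <- sub("@[MF]$", "", colnames(norm))
  groups <- unique(lab)
  out <- matrix(NA_real_, nrow = nrow(norm), ncol = length(groups),
                dimnames = list(rownames(norm), groups))
  for (gp in groups) {
    cols <- which(lab == gp)
    out[, gp] <- rowMeans(norm[, cols, drop = FALSE])
  }
  new_normalized_matrix(out, stage = norm_stage(norm), level = norm_level(norm))
}

#' Median-center gene rows
#'
#' Separates the sex-marker genes (they are reported alongside, not
#' clustered), then subtracts each remaining gene's median across
#' conditions so every row has median zero.
#'
#' @param norm Condition-level `normalized_matrix`.
#' @param sex_markers Gene rows to separate first (default Xist, Ddx3y).
#' @return Centered `normalized_matrix`; the separated marker rows are in
#'   the `sex_marker_values` attribute.
#' @export
median_center <- function(norm, sex_markers = SEX_MARKER_GENES) {
  mk <- intersect(rownames(norm), sex_markers)
  markers <- norm[mk, , drop = FALSE]
  x <- norm[setdiff(rownames(norm), mk), , drop = FALSE]
  med <- apply(x, 1, stats::median)
  out <- new_normalized_matrix(unclass(x) - med, stage = "centered",
                               level = "gene")
  dimnames(out) <- dimnames(x)
  attr(out, "sex_marker_values") <- markers
  out
}

#' Run the whole normalization chain
#'
#' Convenience composition of [log_ratio_normalize()],
#' [collapse_probes()], [median_polish()], [collapse_replicates()] and
#' [median_center()] in the stated order.
#'
#' @param counts QC-filtered wells x probes matrix.
#' @param panel,design Panel and design of the screen.
#' @param pseudocount,tol,max_iter,polish_output Passed through to the
#'   stages.
#' @return List with `probe` (probe x well), `well` (gene x well, after
#'   polish), `condition` (gene x condition) and `centered` matrices.
#' @export
normalize_screen <- function(counts, panel, design, pseudocount = 1,
                             tol = 1e-6, max_iter = 20,
                             polish_output = "residual_plus_row") {
  probe <- log_ratio_normalize(counts, panel, pseudocount)
  gene <- collapse_probes(probe, panel)
  polished <- median_polish(gene, tol = tol, max_iter = max_iter,
                            output = polish_output)
  condition <- collapse_replicates(polished, design)
  centered <- median_center(condition)
  list(probe = probe, well = polished, condition = condition,
       centered = centered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
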