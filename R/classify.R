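# Classification: sex inference, signature aggregation, Pearson
# correlation against reference signatures with the 0.65 retention rule,
# hierarchical clustering and cross-platform concordance.

#' Infer sample sex from the Xist - Ddx3y marker score
#'
#' Positive score (Xist above Ddx3y) calls female, negative calls male,
#' an exact tie is left `unknown`.
#'
#' @param norm Gene-level `normalized_matrix` (well or condition stage)
#'   containing both marker genes.
#' @param markers Length-2 character vector: the X-linked and the Y-linked
#'   marker gene.
#' @return Data frame with `sample`, `score` and `sex` (`"F"`, `"M"` or
#'   `"unknown"`).
#' @export
infer_sex <- function(norm, markers = c("Xist", "Ddx3y")) {
  miss <- setdiff(markers, rownames(norm))
  if (length(miss))
    stop("sex marker gene(s) absent: ", paste(miss, collapse = ", "))
  score <- norm[markers[1], ] - norm[markers[2], ]
  data.frame(sample = colnames(norm), score = as.numeric(score),
             sex = ifelse(score > 0, "F", ifelse(score < 0, "M", "unknown")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate reference profiles into cluster signatures
#'
#' Per cluster and gene, the median of the member chemicals' normalized
#' expression values.
#'
#' @param reference Genes x chemicals matrix of normalized expression.
#' @param membership Named character vector: chemical -> cluster. Every
#'   cluster must have at least one member present in the reference.
#' @param provenance Free-text provenance note stored on the result.
#' @return A `signature_set`: genes x clusters matrix with a `provenance`
#'   attribute.
#' @export
aggregate_signatures <- function(reference, membership,
                                 provenance = "user-supplied") {
  present <- membership[names(membership) %in% colnames(reference)]
  lost <- setdiff(unique(membership), unique(present))
  if (length(lost))
    stop("empty cluster (no members in reference): ",
         paste(lost, collapse = ", "))
  membership <- present
  clusters <- unique(membership)
  if (length(clusters) == 0) stop("no cluster has members in the reference")
  out <- matrix(NA_real_, nrow = nrow(reference), ncol = length(clusters),
                dimnames = list(rownames(reference), clusters))
  for (cl in clusters) {
    members <- names(membership)[membership == cl]
    if (length(members) == 0) stop("empty cluster: ", cl)
    out[, cl] <- apply(reference[, members, drop = FALSE], 1, stats::median)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("signature_set", class(matrix()))
  out
}

#' The packaged six-cluster signature fixture
#'
#' Aggregate signatures corresponding to the six reference chemical
#' clusters, taken from the synthetic effect templates
#' ([cluster_templates()]). These are testing fixtures standing in for the
#' unpublished reference signature values.
#'
#' @param panel Panel whose genes the signatures cover.
#' @return A `signature_set` (genes x C1..C6).
#' @export
fixture_signatures <- function(panel = default_panel()) {
  tpl <- cluster_templates(panel)[, paste0("C", 1:6), drop = FALSE]
  class(tpl) <- c("signature_set", class(matrix()))
  attr(tpl, "provenance") <- "synthetic fixture"
  tpl
}

#' Pearson correlation of every condition against every signature
#'
#' Computed over the intersection of matrix and signature genes (or a
#' caller-supplied subset, e.g. the genes assayed by both platforms).
#' Zero-variance vectors give a missing value, never zero; an overlap
#' below 3 genes gives all-missing values with a warning.
#'
#' @param norm Centered condition-level `normalized_matrix`.
#' @param signatures A `signature_set` (genes x signatures).
#' @param genes Optional gene subset.
#' @return `correlation_table`: conditions x signatures matrix of Pearson
#'   r in `[-1, 1]` (or `NA`).
#' @export
correlate_to_signatures <- function(norm, signatures, genes = NULL) {
  shared <- intersect(rownames(norm), rownames(signatures))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3) {
    warning("fewer than 3 shared genes; correlations undefined")
    out <- matrix(NA_real_, nrow = ncol(norm), ncol = ncol(signatures),
                  dimnames = list(colnames(norm), colnames(signatures)))
  } else {
    out <- suppressWarnings(
      stats::cor(norm[shared, , drop = FALSE],
                 signatures[shared, , drop = FALSE]))
    # zero-variance columns yield NA from cor(); make sure nothing slips
    # through as 0
    sd0 <- apply(norm[shared, , drop = FALSE], 2, stats::sd) == 0
    out[sd0, ] <- NA_real_
  }
  class(out) <- c("correlation_table", class(matrix()))
  attr(out, "genes") <- if (length(shared) >= 3) shared else character(0)
  out
}

parse_condition_labels <- function(labels) {
  parts <- strsplit(labels, "@", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 2 | n > 3))
    stop("malformed condition label(s): ",
         paste(labels[n < 2 | n > 3], collapse = ", "))
  data.frame(
    label = labels,
    chemical_id = vapply(parts, `[`, "", 1),
    concentration_uM = as.numeric(vapply(parts, `[`, "", 2)),
    sex = vapply(parts, function(p) if (length(p) == 3) p[3] else NA_character_,
                 ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify chemicals by their best signature correlations
#'
#' A chemical is retained for a signature when **any** of its
#' concentration (and sex) profiles correlates with that signature
#' strictly above the threshold. Exactly one retained signature classifies
#' the chemical; two or more leave it `unclassified_ambiguous` (flagged
#' with all candidates and, when supplied, its cell-health covariate --
#' never auto-resolved); none leaves it `unclassified_low`.
#'
#' @param corr A `correlation_table` whose row labels parse as
#'   `"chemical@concentration[@sex]"`.
#' @param threshold Retention threshold on Pearson r (default 0.65,
#'   strict `>`).
#' @param health Optional named per-chemical cell-health covariate
#'   (e.g. median spike-in fraction), attached to the output.
#' @return A `classification_result` data frame (one row per chemical:
#'   `status`, assigned `signature`, `candidates`, `max_r`,
#'   `n_supporting`) with per-chemical supporting
#'   (signature, concentration, sex, r) triples in the `supporting`
#'   attribute.
#' @export
assign_clusters <- function(corr, threshold = 0.65, health = NULL) {
  meta <- parse_condition_labels(rownames(corr))
  chems <- unique(meta$chemical_id)
  res <- data.frame(chemical_id = chems, status = NA_character_,
                    signature = NA_character_, candidates = NA_character_,
                    max_r = NA_real_, n_supporting = 0L,
                    row.names = NULL, stringsAsFactors = FALSE)
  supporting <- vector("list", length(chems))
  names(supporting) <- chems
  for (i in seq_along(chems)) {
    rows <- which(meta$chemical_id == chems[i])
    r <- corr[rows, , drop = FALSE]
    res$max_r[i] <- if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
    hit <- which(!is.na(r) & r > threshold, arr.ind = TRUE)
    sigs <- unique(colnames(r)[hit[, 2]])
    if (nrow(hit)) {
      supporting[[i]] <- data.frame(
        signature = colnames(r)[hit[, 2]],
        concentration_uM = meta$concentration_uM[rows][hit[, 1]],
        sex = meta$sex[rows][hit[, 1]],
        r = r[hit],
        row.names = NULL, stringsAsFactors = FALSE)
    }
    res$n_supporting[i] <- nrow(hit)
    if (length(sigs) == 1L) {
      res$status[i] <- "classified"
      res$signature[i] <- sigs
    } else if (length(sigs) > 1L) {
      res$status[i] <- "unclassified_ambiguous"
      res$candidates[i] <- paste(sort(sigs), collapse = ",")
    } else {
      res$status[i] <- "unclassified_low"
    }
  }
  if (!is.null(health))
    res$cell_health <- unname(health[res$chemical_id])
  attr(res, "supporting") <- supporting
  attr(res, "threshold") <- threshold
  class(res) <- c("classification_result", "data.frame")
  res
}

#' @export
print.classification_result <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("Classification of %d chemicals (r > %.2f):\n", nrow(x),
              attr(x, "threshold")))
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  cl <- x[x$status == "classified", , drop = FALSE]
  if (nrow(cl)) {
    st <- table(cl$signature)
    cat("  assigned: ",
        paste(sprintf("%s=%d", names(st), as.integer(st)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Hierarchical clustering of condition profiles
#'
#' Agglomerative clustering of the columns under correlation distance
#' (1 - Pearson r) with average linkage; columns are pre-sorted by label
#' so tied merges resolve deterministically.
#'
#' @param norm Centered `normalized_matrix` with >= 2 columns, no missing
#'   values.
#' @param method Linkage passed to [stats::hclust()].
#' @return An [stats::hclust] tree over the condition columns.
#' @export
hierarchical_cluster <- function(norm, method = "average") {
  if (ncol(norm) < 2) stop("need >= 2 columns to cluster")
  if (any(!is.finite(norm))) stop("missing values in matrix; drop them first")
  x <- norm[, order(colnames(norm)), drop = FALSE]
  r <- suppressWarnings(stats::cor(x))
  if (anyNA(r))
    stop("zero-variance column(s): ",
         paste(colnames(r)[apply(is.na(r), 2, any)], collapse = ", "))
  stats::hclust(stats::as.dist(1 - r), method = method)
}

#' Export an hclust tree as a Newick string
#'
#' @param hc An [stats::hclust] tree.
#' @return Single Newick-format string.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Cross-platform concordance of two expression profiles
#'
#' Pearson correlation over the genes shared by a profile from this assay
#' and an external (e.g. RNA-seq) profile, with a two-sided p-value from
#' the t distribution and the paired per-gene table for scatter plots.
#'
#' @param a,b Named numeric vectors of normalized expression (gene names).
#' @return A `concordance` list: `r`, `p_value`, `n_genes`, `table`.
#' @export
cross_platform_concordance <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("need >= 3 shared genes; got ", length(shared))
  x <- as.numeric(a[shared]); y <- as.numeric(b[shared])
  r <- stats::cor(x, y)
  n <- length(shared)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- list(r = r, p_value = p, n_genes = n,
              table = data.frame(gene = shared, a = x, b = y,
                                 row.names = NULL, stringsAsFactors = FALSE))
  class(out) <- "concordance"
  out
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Cross-platform concordance: r = %.3f (p = %.3g, %d shared genes)\n",
              x$r, x$p_value, x$n_genes))
  invisible(x)
}
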