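# Count matrix IO: wells x probes nonnegative integer read counts.

new_count_matrix <- function(x, provenance = "loaded") {
  stopifnot(is.matrix(x))
  storage.mode(x) <- "integer"
  attr(x, "provenance") <- provenance
  x
}

validate_counts <- function(x, panel = NULL, what = "count matrix") {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have well row names and probe column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate well id: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate probe id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(is.na(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or missing count at well '%s', probe '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  if (!is.null(panel)) {
    orphan <- setdiff(colnames(x), panel$probe_id)
    if (length(orphan))
      stop("probes absent from panel: ", paste(orphan, collapse = ", "))
  }
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' Expects a tab-separated table whose first column holds well identifiers
#' and whose header row holds probe identifiers; every cell must be a
#' nonnegative integer. Malformed cells and duplicate identifiers are
#' rejected with the offending row/column named.
#'
#' @param path File path.
#' @param panel Optional [probe_panel()]; when given, columns must be a
#'   subset of its probes.
#' @return An integer matrix (wells x probes) with a `provenance`
#'   attribute.
#' @export
read_count_matrix <- function(path, panel = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a well column plus >=1 probe")
  wells <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v) || any(!is.finite(v)) || any(v != trunc(v))) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.finite(vn) | vn != trunc(vn) | vn < 0)[1]
      if (!is.na(bad))
        stop(sprintf("malformed count '%s' at well '%s', probe '%s'",
                     as.character(v[bad]), wells[bad], names(vals)[j]))
      vals[[j]] <- vn
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- wells
  validate_counts(x, panel)
  new_count_matrix(x, provenance = paste0("loaded:", path))
}

#' Write a count matrix as TSV
#'
#' @param counts Wells x probes integer matrix.
#' @param path File path; first column is named `well`.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(well = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
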