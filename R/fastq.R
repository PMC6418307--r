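# Synthetic FASTQ dialect and exact-match demultiplexing.
#
# Read layout (this package's own documented dialect, not a claim about the
# real assay's read structure):
#   [8 nt forward barcode][20 nt probe junction][10 nt reverse barcode]
# Forward barcodes index well positions, reverse barcodes index plates;
# demultiplexing is exact-match only.

FWD_BC_WIDTH <- 8L
REV_BC_WIDTH <- 10L
JUNCTION_WIDTH <- 20L

#' Emit synthetic FASTQ reads for a count matrix
#'
#' Writes exactly one read per count, in the package's fixed-width
#' barcode + junction + barcode dialect, shuffled into a seeded random
#' order. [count_fastq()] inverts this exactly (no sequencing errors are
#' simulated).
#'
#' @param counts Wells x probes integer matrix; wells must exist in
#'   `design`, probes in `panel`.
#' @param design A `plate_design` supplying the barcode pair of each well.
#' @param panel A [probe_panel()] with `junction_seq` for every probe.
#' @param path Output FASTQ path.
#' @param seed Integer seed for the read shuffle.
#' @return `path`, invisibly; the number of reads written equals
#'   `sum(counts)`.
#' @export
simulate_fastq <- function(counts, design, panel, path, seed = 1) {
  if (is.null(panel$junction_seq) || anyNA(panel$junction_seq))
    stop("panel has no junction_seq for every probe; FASTQ mode unsupported")
  wid <- design_well_ids(design)
  miss <- setdiff(rownames(counts), wid)
  if (length(miss))
    stop("wells absent from design: ", paste(miss, collapse = ", "))
  fwd <- stats::setNames(design$fwd_barcode, wid)[rownames(counts)]
  rev_bc <- stats::setNames(design$rev_barcode, wid)[rownames(counts)]
  junc <- stats::setNames(panel$junction_seq, panel$probe_id)[colnames(counts)]
  idx <- which(counts > 0, arr.ind = TRUE)
  seqs <- character(0)
  if (nrow(idx)) {
    n <- counts[idx]
    seqs <- paste0(rep(fwd[idx[, 1]], n),
                   rep(junc[idx[, 2]], n),
                   rep(rev_bc[idx[, 1]], n))
    set.seed(seed)
    seqs <- seqs[sample.int(length(seqs))]
  }
  dss <- Biostrings::DNAStringSet(seqs)
  if (length(dss)) names(dss) <- sprintf("read%07d", seq_along(dss))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Count reads per well and probe from synthetic FASTQ
#'
#' Exact-match demultiplexing of reads in the package's synthetic dialect
#' (see [simulate_fastq()]): the forward barcode / reverse barcode pair
#' selects the well, the junction sequence selects the probe. Reads whose
#' barcode pair or junction matches nothing are tallied as unassigned.
#'
#' @param path FASTQ file.
#' @param design A `plate_design`.
#' @param panel A [probe_panel()] with junction sequences.
#' @return Integer count matrix over all design wells x all panel probes
#'   (zeros where no read matched), with attribute `unassigned` holding the
#'   number of unassignable reads. Assigned + unassigned reads always equal
#'   the number of input reads.
#' @export
count_fastq <- function(path, design, panel) {
  if (is.null(panel$junction_seq) || anyNA(panel$junction_seq))
    stop("panel has no junction_seq for every probe; FASTQ mode unsupported")
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  wid <- design_well_ids(design)
  well_of_pair <- stats::setNames(seq_along(wid),
                                  paste0(design$fwd_barcode, design$rev_barcode))
  probe_of_junc <- stats::setNames(seq_len(nrow(panel)), panel$junction_seq)
  counts <- matrix(0L, nrow = length(wid), ncol = nrow(panel),
                   dimnames = list(wid, panel$probe_id))
  unassigned <- 0L
  if (length(reads)) {
    len <- nchar(reads)
    ok_len <- len == FWD_BC_WIDTH + JUNCTION_WIDTH + REV_BC_WIDTH
    unassigned <- unassigned + sum(!ok_len)
    reads <- reads[ok_len]
    if (length(reads)) {
      pair <- paste0(substr(reads, 1L, FWD_BC_WIDTH),
                     substr(reads, FWD_BC_WIDTH + JUNCTION_WIDTH + 1L,
                            FWD_BC_WIDTH + JUNCTION_WIDTH + REV_BC_WIDTH))
      junc <- substr(reads, FWD_BC_WIDTH + 1L, FWD_BC_WIDTH + JUNCTION_WIDTH)
      wi <- well_of_pair[pair]
      pi <- probe_of_junc[junc]
      hit <- !is.na(wi) & !is.na(pi)
      unassigned <- unassigned + sum(!hit)
      if (any(hit)) {
        enc <- (wi[hit] - 1L) + nrow(counts) * (pi[hit] - 1L) + 1L
        tab <- tabulate(enc, nbins = length(counts))
        counts[] <- counts + as.integer(tab)
      }
    }
  }
  counts <- new_count_matrix(counts, provenance = paste0("fastq:", path))
  attr(counts, "unassigned") <- unassigned
  counts
}
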