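# Plate design: the well-level experiment layout with dual barcodes.

VEHICLE_ID <- "VEHICLE"

plate_geometry <- function(plate_size) {
  switch(as.character(plate_size),
         "384" = list(nrow = 16L, ncol = 24L),
         "96"  = list(nrow = 8L,  ncol = 12L),
         stop("plate_size must be 96 or 384"))
}

#' Canonical well identifier
#'
#' All modules join well-level tables on `"{plate_id}:{row}{col}"`, e.g.
#' `"plate01:A01"`.
#'
#' @param plate_id,row,col Plate label, row letter, column number.
#' @return Character vector of well ids.
#' @export
well_id <- function(plate_id, row, col) {
  sprintf("%s:%s%02d", plate_id, row, as.integer(col))
}

#' Lay out a screening design on multi-well plates
#'
#' Places every (chemical, concentration) pair once per sex per biological
#' replicate, fills the remaining wells of each plate with vehicle controls
#' (interspersed at evenly spaced positions), and assigns a unique dual
#' barcode to every well (forward barcode indexed by well position, reverse
#' barcode by plate, so every pair is unique across the experiment).
#'
#' The defaults reproduce the screen's scale: 352 chemical slots x 4
#' concentrations x 2 sexes x 3 replicates on twenty-four 384-well plates
#' (4 male + 4 female plates per replicate), 9,216 uniquely barcoded wells.
#'
#' @param chemicals Character vector of chemical identifiers (may include
#'   repeats of a compound under distinct slot ids). `"VEHICLE"` is
#'   reserved.
#' @param n_replicates Biological replicates (each on its own plates).
#' @param sexes Character vector, subset of `c("M", "F")`.
#' @param concentrations Dosing series in micromolar; vehicle wells carry 0.
#' @param plate_size 96 or 384.
#' @param min_vehicle_per_plate Minimum vehicle wells interspersed on every
#'   plate.
#' @param max_plates Optional budget; a layout needing more plates raises a
#'   sizing error stating the required count.
#' @param seed Integer seed controlling chemical placement within plates.
#' @return A `plate_design` data frame (one row per well) with columns
#'   `plate_id, row, col, chemical_id, concentration_uM, sex, replicate,
#'   fwd_barcode, rev_barcode`.
#' @export
make_design <- function(chemicals = default_chemicals(),
                        n_replicates = 3,
                        sexes = c("M", "F"),
                        concentrations = c(0.01, 0.1, 1, 10),
                        plate_size = 384,
                        min_vehicle_per_plate = 8,
                        max_plates = NULL,
                        seed = 1) {
  stopifnot(length(chemicals) >= 1, length(concentrations) >= 1,
            n_replicates >= 1, all(sexes %in% c("M", "F")),
            !anyDuplicated(chemicals))
  if (VEHICLE_ID %in% chemicals)
    stop("'", VEHICLE_ID, "' is reserved for vehicle wells")
  geom <- plate_geometry(plate_size)
  n_treat <- length(chemicals) * length(concentrations)
  capacity <- plate_size - min_vehicle_per_plate
  plates_per_block <- ceiling(n_treat / capacity)
  n_blocks <- n_replicates * length(sexes)
  n_plates <- plates_per_block * n_blocks
  if (!is.null(max_plates) && n_plates > max_plates)
    stop(sprintf("design needs %d plates (%d per sex-replicate block) but only %d allowed",
                 n_plates, plates_per_block, max_plates))
  set.seed(seed)
  fwd <- make_kmers(plate_size, width = 8L)
  rev <- make_kmers(n_plates, width = 10L)

  plate_counter <- 0L
  blocks <- expand.grid(sex = sexes, replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    treat <- expand.grid(chemical_id = chemicals,
                         concentration_uM = concentrations,
                         stringsAsFactors = FALSE)
    treat <- treat[sample.int(nrow(treat)), ]  # randomized placement
    # split treatments as evenly as possible over this block's plates
    plate_of <- rep(seq_len(plates_per_block), length.out = nrow(treat))
    plate_of <- sort(plate_of)
    rows <- vector("list", plates_per_block)
    for (p in seq_len(plates_per_block)) {
      plate_counter <- plate_counter + 1L
      pid <- sprintf("plate%02d", plate_counter)
      tr <- treat[plate_of == p, , drop = FALSE]
      n_veh <- plate_size - nrow(tr)
      if (n_veh < min_vehicle_per_plate)
        stop("internal sizing error: vehicle wells below minimum")
      pos_veh <- floor(seq(1, plate_size, length.out = n_veh))
      pos_tr <- setdiff(seq_len(plate_size), pos_veh)
      pos <- integer(plate_size)
      chem <- character(plate_size)
      conc <- numeric(plate_size)
      chem[pos_veh] <- VEHICLE_ID
      conc[pos_veh] <- 0
      chem[pos_tr] <- tr$chemical_id
      conc[pos_tr] <- tr$concentration_uM
      idx <- seq_len(plate_size)
      rows[[p]] <- data.frame(
        plate_id = pid,
        row = LETTERS[(idx - 1L) %/% geom$ncol + 1L],
        col = (idx - 1L) %% geom$ncol + 1L,
        chemical_id = chem,
        concentration_uM = conc,
        sex = blocks$sex[b],
        replicate = blocks$replicate[b],
        fwd_barcode = fwd[idx],
        rev_barcode = rev[plate_counter],
        stringsAsFactors = FALSE)
    }
    out[[b]] <- do.call(rbind, rows)
  }
  design <- do.call(rbind, out)
  rownames(design) <- NULL
  class(design) <- c("plate_design", "data.frame")
  attr(design, "plate_size") <- plate_size
  validate_design(design)
  design
}

#' Default chemical slot labels for a full-scale screen
#'
#' 352 slots: a handful of named hallmark compounds plus anonymous slots,
#' so that 352 chemicals x 4 concentrations plus 128 vehicle wells fill
#' each 4-plate sex-replicate block of a 384-well screen exactly.
#'
#' @param n Number of slots.
#' @return Character vector of chemical ids.
#' @export
default_chemicals <- function(n = 352) {
  named <- c("bifenthrin", "fenpropathrin", "esfenvalerate", "NMDA",
             "pyraclostrobin", "trifloxystrobin", "azoxystrobin",
             "kresoxim-methyl", "fenamidone", "fenpyroximate", "rotenone",
             "diquat_dibromide", "fluazinam", "topotecan", "camptothecin",
             "JQ1")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("chem%03d", seq_len(n - length(named))))
}

validate_design <- function(design) {
  need <- c("plate_id", "row", "col", "chemical_id", "concentration_uM",
            "sex", "replicate", "fwd_barcode", "rev_barcode")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("plate map missing column(s): ", paste(miss, collapse = ", "))
  plate_size <- attr(design, "plate_size")
  if (is.null(plate_size)) plate_size <- 384
  geom <- plate_geometry(plate_size)
  bad_row <- !design$row %in% LETTERS[seq_len(geom$nrow)]
  if (any(bad_row))
    stop("well row outside A-", LETTERS[geom$nrow], ": ",
         paste(unique(design$row[bad_row]), collapse = ", "))
  bad_col <- design$col < 1 | design$col > geom$ncol
  if (any(bad_col))
    stop("well column outside 1-", geom$ncol, ": ",
         paste(unique(design$col[bad_col]), collapse = ", "))
  pair <- paste(design$fwd_barcode, design$rev_barcode, sep = "+")
  if (anyDuplicated(pair)) {
    d <- pair[duplicated(pair)][1]
    wells <- design_well_ids(design)[pair == d]
    stop("duplicate barcode pair ", d, " shared by wells: ",
         paste(wells, collapse = ", "))
  }
  per_plate <- table(design$plate_id)
  if (any(per_plate > plate_size))
    stop("plate(s) over capacity (", plate_size, " wells): ",
         paste(names(per_plate)[per_plate > plate_size], collapse = ", "))
  veh <- design$chemical_id == VEHICLE_ID
  if (any(design$concentration_uM[veh] != 0))
    stop("vehicle wells must have concentration 0")
  if (any(design$concentration_uM[!veh] <= 0))
    stop("treated wells must have positive concentration")
  if (anyDuplicated(design_well_ids(design)))
    stop("duplicate well position within a plate")
  invisible(design)
}

#' Well identifiers of a design
#'
#' @param design A `plate_design`.
#' @return Canonical [well_id()] per well, in design row order.
#' @export
design_well_ids <- function(design) {
  well_id(design$plate_id, design$row, design$col)
}

#' Condition label for each well
#'
#' `"chemical@concentration@sex"` -- the chemical-concentration-sex triple
#' a well belongs to; biological replicates share a label.
#'
#' @param design A `plate_design`.
#' @param with_sex Drop the sex field when `FALSE`.
#' @return Character vector, one label per well.
#' @export
condition_labels <- function(design, with_sex = TRUE) {
  conc <- vapply(design$concentration_uM,
                 function(z) format(z, trim = TRUE, scientific = FALSE),
                 character(1))
  if (with_sex)
    paste(design$chemical_id, conc, design$sex, sep = "@")
  else
    paste(design$chemical_id, conc, sep = "@")
}

#' Read / write a plate map as TSV
#'
#' @param path File path to a tab-separated plate map with the columns
#'   produced by [make_design()].
#' @param plate_size Plate geometry used for validation.
#' @return `read_plate_map()` returns a validated `plate_design`.
#' @export
read_plate_map <- function(path, plate_size = 384) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$col <- as.integer(df$col)
  df$replicate <- as.integer(df$replicate)
  df$concentration_uM <- as.numeric(df$concentration_uM)
  class(df) <- c("plate_design", "data.frame")
  attr(df, "plate_size") <- plate_size
  validate_design(df)
  df
}

#' @param design A `plate_design`.
#' @rdname read_plate_map
#' @export
write_plate_map <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf(
    "Plate design: %d wells on %d plates (%d replicates, sexes: %s)\n",
    nrow(x), length(unique(x$plate_id)), length(unique(x$replicate)),
    paste(sort(unique(x$sex)), collapse = "/")))
  cat(sprintf("  %d chemicals at %d concentrations; %d vehicle wells\n",
              length(setdiff(unique(x$chemical_id), VEHICLE_ID)),
              length(unique(x$concentration_uM[x$concentration_uM > 0])),
              sum(x$chemical_id == VEHICLE_ID)))
  invisible(x)
}
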