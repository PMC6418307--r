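# Synthetic screen generator: negative-binomial counts with well-level
# library-size variation, spike-in competition coupled to viability,
# dose-dependent chemical effects, sex markers, and sporadic failures.

TEMPLATE_LABELS <- c("C1", "C2", "C3", "C4", "C5", "C6", "novel", "null")
DOSE_MODELS <- c("flat", "threshold", "monotone")

#' Reference cluster effect templates (synthetic fixture)
#'
#' Hand-authored log2 fold-change templates for the six previously defined
#' chemical clusters plus a novel (JQ1-like) and a null template, on the
#' genes of [default_panel()]. Directions follow the published
#' phenomenology -- e.g. the Cluster-2-like (electron-transport-inhibitor)
#' template raises Hmox1, Fos, Cx3cr1 and Gsta4 and lowers Rbfox3, Syt1
#' and Nrxn1; the JQ1-like template lowers microglial/astrocytic markers
#' (Cx3cr1, Trem2, Aqp4) and raises Fos, Rest and Nrxn1 -- but magnitudes
#' are fixtures for simulation and testing, not reconstructions of
#' unpublished signature values. Control genes and sex markers are always
#' zero.
#'
#' @param panel A [probe_panel()]; templates cover its genes.
#' @return Numeric matrix, genes x templates (`C1..C6`, `novel`, `null`).
#' @export
cluster_templates <- function(panel = default_panel()) {
  genes <- setdiff(unique(panel$gene), SPIKE_GENE)
  tpl <- matrix(0, nrow = length(genes), ncol = length(TEMPLATE_LABELS),
                dimnames = list(genes, TEMPLATE_LABELS))
  set_fx <- function(label, fx) {
    g <- intersect(names(fx), genes)
    tpl[g, label] <<- fx[g]
  }
  # C1: pyrethroid-like, immediate early gene induction
  set_fx("C1", c(Fos = 2.0, Egr1 = 1.8, Arc = 1.6, Npas4 = 1.5, Junb = 1.4,
                 Fosb = 1.2, Vgf = 1.0, Bdnf = 1.0, Homer1 = 0.8))
  # C2: mitochondrial electron-transport inhibitors; stress/immune up,
  # synaptic down (autism/neurodegeneration-like)
  set_fx("C2", c(Hmox1 = 2.0, Gsta4 = 1.6, Cx3cr1 = 1.4, Fos = 1.2,
                 Nqo1 = 1.2, Sod2 = 1.0, Gsn = 0.8,
                 Rbfox3 = -1.4, Syt1 = -1.2, Nrxn1 = -1.0, Snap25 = -0.8))
  # C3: cytoskeletal remodelling
  set_fx("C3", c(Gsn = 1.5, Pdlim2 = 1.4, Tlr4 = 0.6,
                 Ank2 = -0.8, Mapt = -0.6, App = -0.5))
  # C4: inflammatory cytokine response
  set_fx("C4", c(Tnf = 1.8, Il1b = 1.6, Ccl2 = 1.5, C1qa = 1.2, Gfap = 1.0))
  # C5: topoisomerase inhibitors, long synaptic genes down
  set_fx("C5", c(Nrxn1 = -1.8, Nrxn3 = -1.6, Cntnap2 = -1.6, Nlgn1 = -1.4,
                 Ank2 = -1.2, Grin2b = -1.0, Scn2a = -1.0, Top2b = -0.8))
  # C6: neuronal identity shift
  set_fx("C6", c(Mecp2 = 0.8, Foxp1 = 0.8, Mef2c = 0.6,
                 Camk2a = -0.6, Gad1 = -0.8, Gabra1 = -0.6))
  # novel: JQ1-like epigenetic modifier
  set_fx("novel", c(Cx3cr1 = -1.6, Trem2 = -1.5, Aqp4 = -1.2, C1qa = -1.0,
                    Fos = 1.2, Rest = 1.2, Nrxn1 = 0.8))
  ctrl_or_sex <- genes %in% c(CONTROL_GENES, SEX_MARKER_GENES)
  tpl[ctrl_or_sex, ] <- 0
  tpl
}

#' Per-chemical effect profiles
#'
#' Binds every chemical to an effect template, a dose-response model and a
#' viability, producing the per-gene log2 fold-changes the simulator
#' applies at the reference (highest) concentration. Vehicle wells always
#' get the identically-zero profile; control genes and spike probes carry
#' fold-change 0 by construction (they define the normalization scale).
#'
#' Dose models scale the reference effect by concentration rank:
#' `flat` = full effect at every concentration, `threshold` = full effect
#' only at the top concentration, `monotone` = effect proportional to the
#' concentration's rank in the dosing series.
#'
#' @param chemicals Character vector of chemical ids.
#' @param template Template label per chemical (recycled), from
#'   `colnames(templates)`.
#' @param dose_model `"flat"`, `"threshold"` or `"monotone"` per chemical
#'   (recycled).
#' @param viability Viability in (0, 1] per chemical (recycled); applied at
#'   full strength where the dose model is active, e.g. viability 0.4 with
#'   a flat dose model gives 0.4 at every concentration.
#' @param templates Genes x templates matrix, by default
#'   [cluster_templates()].
#' @param sex_mult Optional genes x chemicals matrix of per-gene
#'   multipliers applied to female wells (default 1 = no sex interaction).
#' @return An `effect_profiles` list with elements `lfc` (genes x
#'   chemicals), `template`, `dose_model`, `viability`, `sex_mult`.
#' @export
effect_profiles <- function(chemicals, template = "null",
                            dose_model = "flat", viability = 1,
                            templates = cluster_templates(),
                            sex_mult = NULL) {
  stopifnot(!anyDuplicated(chemicals))
  template <- rep_len(as.character(template), length(chemicals))
  dose_model <- rep_len(as.character(dose_model), length(chemicals))
  viability <- rep_len(as.numeric(viability), length(chemicals))
  bad <- setdiff(unique(template), colnames(templates))
  if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(dose_model), DOSE_MODELS)
  if (length(bad)) stop("unknown dose model(s): ", paste(bad, collapse = ", "))
  if (any(viability <= 0 | viability > 1))
    stop("viability must be in (0, 1]")
  lfc <- templates[, template, drop = FALSE]
  colnames(lfc) <- chemicals
  out <- list(lfc = lfc,
              template = stats::setNames(template, chemicals),
              dose_model = stats::setNames(dose_model, chemicals),
              viability = stats::setNames(viability, chemicals),
              sex_mult = sex_mult)
  class(out) <- "effect_profiles"
  out
}

#' Simulation configuration
#'
#' All tunables of the synthetic screen generator. Defaults describe a
#' typical targeted screen: median library size ~20,000 reads per well
#' with moderate log-normal spread, negative-binomial dispersion 0.05,
#' a 5% luciferase spike-in read share at full viability, sporadic
#' well/probe dropout, and a 4-log2-unit Xist/Ddx3y separation between
#' the sexes.
#'
#' @param seed Mandatory integer seed; the generator has no implicit
#'   randomness.
#' @param lib_meanlog,lib_sdlog Log-normal parameters of the per-well
#'   library size (reads).
#' @param dispersion Negative-binomial dispersion (1/size); shared by all
#'   probes.
#' @param spike_fraction Expected spike-in read fraction in a healthy,
#'   effect-free well.
#' @param well_fail_prob,probe_fail_prob Probability that a well
#'   (resp. probe) fails outright; failed wells are resampled to a total
#'   below 500 reads, failed probes are zeroed everywhere.
#' @param sex_effect Log2 separation applied to Xist (up in F) and Ddx3y
#'   (up in M); the marker score Xist - Ddx3y then separates the sexes by
#'   ~2 x `sex_effect`... the two markers share one baseline so the score
#'   isolates the effect.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression weights (drawn once per simulation from
#'   `seed`).
#' @param baseline_weights Optional named per-gene weights overriding the
#'   draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       lib_meanlog = log(20000), lib_sdlog = 0.4,
                       dispersion = 0.05,
                       spike_fraction = 0.05,
                       well_fail_prob = 0.01, probe_fail_prob = 0.005,
                       sex_effect = 4,
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       baseline_weights = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config: seed is mandatory")
  stopifnot(dispersion > 0,
            well_fail_prob >= 0, well_fail_prob <= 1,
            probe_fail_prob >= 0, probe_fail_prob <= 1,
            spike_fraction > 0, spike_fraction < 1)
  out <- list(seed = as.integer(seed), lib_meanlog = lib_meanlog,
              lib_sdlog = lib_sdlog, dispersion = dispersion,
              spike_fraction = spike_fraction,
              well_fail_prob = well_fail_prob,
              probe_fail_prob = probe_fail_prob,
              sex_effect = sex_effect,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              baseline_weights = baseline_weights)
  class(out) <- "sim_config"
  out
}

dose_factor <- function(model, conc, conc_levels) {
  conc_levels <- sort(unique(conc_levels[conc_levels > 0]))
  f <- numeric(length(conc))
  active <- conc > 0
  rank_ <- match(conc, conc_levels)
  f[active & model == "flat"] <- 1
  thr <- active & model == "threshold"
  f[thr] <- as.numeric(conc[thr] == max(conc_levels))
  mono <- active & model == "monotone"
  f[mono] <- rank_[mono] / length(conc_levels)
  f
}

#' Simulate a screen's count matrix with known ground truth
#'
#' The generative model, per well: a library size `L ~ LogNormal`; each
#' gene's cellular expression is its baseline weight times
#' `2^(template effect x dose factor)`, partitioned equally over the
#' gene's probes; the luciferase spike-in competes with cellular
#' transcripts for the read budget, so reduced viability (fewer live
#' cells) yields a higher spike read fraction; probe counts are
#' negative-binomial around their expected share of `L`. Xist is elevated
#' in female wells and Ddx3y in male wells by the configured effect size.
#' Failed wells are redrawn to a total under 500 reads; failed probes are
#' zeroed everywhere. Identical seed and inputs give identical output.
#'
#' @param design A `plate_design`.
#' @param panel A [probe_panel()] containing control, spike and sex-marker
#'   probes.
#' @param profiles [effect_profiles()] covering every chemical in the
#'   design.
#' @param config A [sim_config()].
#' @return A list with `counts` (wells x probes integer matrix) and
#'   `truth` (a `ground_truth` list: per-chemical template labels,
#'   per-well sex/viability/failure, per-probe failure, plus the realized
#'   baseline weights and expected per-gene mean counts in an unfailed,
#'   effect-free well).
#' @export
simulate_counts <- function(design, panel, profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  chems <- setdiff(unique(design$chemical_id), VEHICLE_ID)
  miss <- setdiff(chems, colnames(profiles$lfc))
  if (length(miss))
    stop("no effect profile for chemical(s): ", paste(miss, collapse = ", "))

  cellular <- panel[panel$role != "spike", , drop = FALSE]
  spike <- panel[panel$role == "spike", , drop = FALSE]
  if (nrow(spike) == 0) stop("panel has no spike probes")
  genes <- unique(cellular$gene)
  miss <- setdiff(genes, rownames(profiles$lfc))
  if (length(miss))
    stop("profiles lack gene(s): ", paste(miss, collapse = ", "))

  set.seed(config$seed)
  # baseline expression weights per gene (shared marker baseline so the
  # Xist - Ddx3y score isolates the sex effect)
  if (is.null(config$baseline_weights)) {
    w <- stats::setNames(
      stats::rlnorm(length(genes), config$baseline_meanlog, config$baseline_sdlog),
      genes)
  } else {
    w <- config$baseline_weights[genes]
    if (anyNA(w)) stop("baseline_weights must cover every panel gene")
  }
  if (all(SEX_MARKER_GENES %in% genes))
    w[SEX_MARKER_GENES] <- exp(config$baseline_meanlog)
  if (any(w[intersect(CONTROL_GENES, genes)] <= 0))
    stop("control gene with zero baseline mean")

  n_well <- nrow(design)
  wells <- design_well_ids(design)
  chem <- design$chemical_id
  conc <- design$concentration_uM
  sexes <- design$sex

  # per-well gene-level log2 effects
  lfc <- matrix(0, nrow = length(genes), ncol = n_well,
                dimnames = list(genes, NULL))
  treated <- chem != VEHICLE_ID
  df <- numeric(n_well)
  if (any(treated)) {
    model <- profiles$dose_model[chem[treated]]
    df[treated] <- dose_factor(model, conc[treated], conc)
    lfc[, treated] <- profiles$lfc[genes, chem[treated], drop = FALSE] *
      rep(df[treated], each = length(genes))
    if (!is.null(profiles$sex_mult)) {
      fem <- treated & sexes == "F"
      if (any(fem))
        lfc[, fem] <- lfc[, fem] *
          profiles$sex_mult[genes, chem[fem], drop = FALSE]
    }
  }
  if (all(SEX_MARKER_GENES %in% genes)) {
    sgn <- ifelse(sexes == "F", 1, -1)
    lfc["Xist", ] <- lfc["Xist", ] + sgn * config$sex_effect / 2
    lfc["Ddx3y", ] <- lfc["Ddx3y", ] - sgn * config$sex_effect / 2
  }

  # viability: full penalty where the dose model is active
  viab <- rep(1, n_well)
  viab[treated] <- 1 - (1 - profiles$viability[chem[treated]]) * df[treated]

  # expected probe-level expression mass
  np <- table(cellular$gene)[cellular$gene]
  e <- (w[cellular$gene] / as.numeric(np)) * 2^lfc[cellular$gene, , drop = FALSE]
  cell_mass <- viab * colSums(e)
  spike_mass <- config$spike_fraction / (1 - config$spike_fraction) * sum(w)
  total_mass <- cell_mass + spike_mass

  L <- stats::rlnorm(n_well, config$lib_meanlog, config$lib_sdlog)
  mu_cell <- e * rep(viab * L / total_mass, each = nrow(cellular))
  mu_spike <- matrix(rep(L * spike_mass / (nrow(spike) * total_mass),
                         each = nrow(spike)),
                     nrow = nrow(spike))
  mu <- rbind(mu_cell, mu_spike)
  rownames(mu) <- c(cellular$probe_id, spike$probe_id)

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  probe_failed <- stats::runif(nrow(mu)) < config$probe_fail_prob
  counts[probe_failed, ] <- 0L

  well_failed <- stats::runif(n_well) < config$well_fail_prob
  for (i in which(well_failed)) {
    tot <- sample(0:400, 1)
    p <- mu[, i] + 1e-12
    p[probe_failed] <- 0
    counts[, i] <- if (sum(p) > 0) stats::rmultinom(1, tot, p) else 0L
  }

  counts <- t(counts)
  rownames(counts) <- wells
  counts <- counts[, panel$probe_id, drop = FALSE]  # panel column order
  counts <- new_count_matrix(counts, provenance = "simulated")

  expected_mean <- exp(config$lib_meanlog + config$lib_sdlog^2 / 2) *
    w / (sum(w) + spike_mass)
  truth <- list(
    chemical = data.frame(chemical_id = names(profiles$template),
                          template = unname(profiles$template),
                          stringsAsFactors = FALSE),
    well = data.frame(well_id = wells, chemical_id = chem,
                      concentration_uM = conc, sex = sexes,
                      viability = viab, failed = well_failed,
                      stringsAsFactors = FALSE),
    probe = data.frame(probe_id = rownames(mu), failed = probe_failed,
                       stringsAsFactors = FALSE),
    baseline_weights = w,
    expected_gene_mean = expected_mean)
  class(truth) <- "ground_truth"
  list(counts = counts, truth = truth)
}
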