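# Shared fixtures and independent oracles for the test suite.

# Small panel: 3 probes for one target gene, one probe per control gene,
# one probe per sex marker, one spike probe.
tiny_panel <- function(junctions = FALSE) {
  genes <- c("g1", "g1", "g1", "Ascl3", "Psmd4", "Sdha", "Tbp",
             "Xist", "Ddx3y", "Luciferase")
  roles <- c(rep("target", 3), rep("control", 4),
             rep("sex_marker", 2), "spike")
  ids <- c("g1_p1", "g1_p2", "g1_p3", "Ascl3_p1", "Psmd4_p1", "Sdha_p1",
           "Tbp_p1", "Xist_p1", "Ddx3y_p1", "Luc_p1")
  junc <- if (junctions) raslscreen:::make_kmers(length(ids), 20L) else NULL
  probe_panel(ids, genes, roles, junction_seq = junc)
}

tiny_design <- function(n_chem = 2, n_replicates = 1, sexes = "M",
                        plate_size = 96, seed = 1) {
  make_design(sprintf("chem%02d", seq_len(n_chem)),
              n_replicates = n_replicates, sexes = sexes,
              concentrations = c(0.1, 10), plate_size = plate_size,
              seed = seed)
}

rand_counts <- function(n_wells, n_probes, lambda = 50, seed = 1,
                        probes = sprintf("p%02d", seq_len(n_probes))) {
  set.seed(seed)
  m <- matrix(rpois(n_wells * n_probes, lambda), nrow = n_wells,
              dimnames = list(sprintf("plate01:A%02d", seq_len(n_wells)),
                              probes))
  storage.mode(m) <- "integer"
  m
}

# Independent sweep-by-sweep median-polish oracle: explicit loops, no
# shared code with the implementation. Row sweep first, then column sweep;
# returns per-sweep residual snapshots so agreement can be checked sweep by
# sweep.
oracle_polish <- function(x, max_iter = 20, tol = 1e-6) {
  r <- unclass(x)
  row_eff <- rep(0, nrow(r))
  col_eff <- rep(0, ncol(r))
  overall <- 0
  snapshots <- list()
  for (it in seq_len(max_iter)) {
    r_prev <- r
    for (i in seq_len(nrow(r))) {
      m <- median(r[i, ])
      r[i, ] <- r[i, ] - m
      row_eff[i] <- row_eff[i] + m
    }
    m <- median(col_eff)
    col_eff <- col_eff - m
    overall <- overall + m
    for (j in seq_len(ncol(r))) {
      m <- median(r[, j])
      r[, j] <- r[, j] - m
      col_eff[j] <- col_eff[j] + m
    }
    m <- median(row_eff)
    row_eff <- row_eff - m
    overall <- overall + m
    snapshots[[it]] <- r
    if (max(abs(r - r_prev)) < tol) break
  }
  list(residuals = r, row = row_eff, col = col_eff, overall = overall,
       snapshots = snapshots)
}

# Brute-force per-cell log-ratio oracle.
oracle_log_ratio <- function(counts, panel, pseudocount = 1) {
  ctrl <- panel$probe_id[panel$role == "control"]
  ctrl <- intersect(colnames(counts), ctrl)
  out <- matrix(NA_real_, nrow = ncol(counts), ncol = nrow(counts),
                dimnames = list(colnames(counts), rownames(counts)))
  for (w in rownames(counts)) {
    gm <- prod(counts[w, ctrl] + pseudocount)^(1 / length(ctrl))
    for (p in colnames(counts))
      out[p, w] <- log2((counts[w, p] + pseudocount) / gm)
  }
  out
}

# Panel with strong, well-separated templates for recovery experiments.
recovery_screen <- function(seed, n_per_template = 6, n_null = 20,
                            n_replicates = 3,
                            well_fail_prob = 0.01,
                            probe_fail_prob = 0.005) {
  chems <- c(sprintf("c1_%02d", seq_len(n_per_template)),
             sprintf("c2_%02d", seq_len(n_per_template)),
             sprintf("c5_%02d", seq_len(n_per_template)),
             "thresh_c2", "flat_c2", sprintf("nov_%02d", 1:2),
             sprintf("null_%02d", seq_len(n_null)))
  template <- c(rep("C1", n_per_template), rep("C2", n_per_template),
                rep("C5", n_per_template), "C2", "C2", rep("novel", 2),
                rep("null", n_null))
  dose <- rep("flat", length(chems))
  dose[chems == "thresh_c2"] <- "threshold"
  panel <- default_panel()
  profiles <- effect_profiles(chems, template = template, dose_model = dose,
                              templates = cluster_templates(panel))
  design <- make_design(chems, n_replicates = n_replicates,
                        seed = seed)
  cfg <- sim_config(seed = seed, well_fail_prob = well_fail_prob,
                    probe_fail_prob = probe_fail_prob)
  sim <- simulate_counts(design, panel, profiles, cfg)
  list(panel = panel, design = design, profiles = profiles,
       sim = sim, config = cfg)
}
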