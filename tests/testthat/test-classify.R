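test_that("sex inference follows the sign of Xist - Ddx3y with ties unknown", {
  v <- matrix(c(2, -1,
                0.5, 0.5,
                -3, 1), nrow = 2,
              dimnames = list(c("Xist", "Ddx3y"), c("s1", "s2", "s3")))
  nm <- raslscreen:::new_normalized_matrix(v, "condition", "gene")
  calls <- infer_sex(nm)
  expect_equal(calls$sex, c("F", "unknown", "M"))
  expect_equal(calls$score, c(3, 0, -4))
  expect_error(infer_sex(nm[c("Xist", "Xist"), ]), "absent")
})

test_that("sex calls match ground truth for all unfailed wells at default effect size", {
  scr <- recovery_screen(seed = 31, n_per_template = 2, n_null = 4,
                         n_replicates = 1)
  qc <- qc_screen(scr$sim$counts, scr$panel)
  probe <- log_ratio_normalize(qc$counts, scr$panel)
  gene <- collapse_probes(probe, scr$panel)
  calls <- infer_sex(gene)
  truth <- scr$sim$truth$well
  ok <- !truth$failed[match(calls$sample, truth$well_id)]
  expect_equal(calls$sex[ok],
               truth$sex[match(calls$sample, truth$well_id)][ok])
})

test_that("signatures aggregate cluster members by per-gene medians", {
  ref <- matrix(c(1, 2,
                  4, 8,
                  0, 6), nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), c("chem1", "chem2")))
  # singleton cluster: signature equals the member's profile
  sig <- aggregate_signatures(ref, c(chem1 = "K1", chem2 = "K2"))
  expect_equal(unname(sig[, "K1"]), c(1, 4, 0))
  # two members: even-count median is the midpoint
  sig2 <- aggregate_signatures(ref, c(chem1 = "K", chem2 = "K"))
  expect_equal(unname(sig2[, "K"]), c(1.5, 6, 3))
  expect_error(aggregate_signatures(ref, c(ghost = "K9")), "empty cluster")
  # groupby-median oracle on random references
  set.seed(12)
  ref_r <- matrix(rnorm(40), nrow = 4,
                  dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  member <- setNames(rep(c("A", "B", "C"), length.out = 10),
                     colnames(ref_r))
  sig_r <- aggregate_signatures(ref_r, member)
  for (cl in unique(member))
    expect_equal(unname(sig_r[, cl]),
                 unname(apply(ref_r[, names(member)[member == cl],
                                    drop = FALSE], 1, median)))
})

test_that("correlation table hits the exact values and missing-value policy", {
  sig <- fixture_signatures()
  genes <- rownames(sig)
  x <- cbind(same = sig[, "C2"], flipped = -sig[, "C2"],
             flat = rep(0.3, length(genes)))
  rownames(x) <- genes
  colnames(x) <- c("a@10@M", "b@10@M", "c@10@M")
  nm <- raslscreen:::new_normalized_matrix(x, "centered", "gene")
  corr <- correlate_to_signatures(nm, sig)
  expect_equal(corr["a@10@M", "C2"], 1)
  expect_equal(corr["b@10@M", "C2"], -1)
  expect_true(all(is.na(corr["c@10@M", ])))  # zero variance -> missing, not 0
  expect_true(all(abs(corr[!is.na(corr)]) <= 1))
  # too little overlap is all-missing with a warning
  expect_warning(small <- correlate_to_signatures(nm[1:2, ], sig),
                 "fewer than 3 shared genes")
  expect_true(all(is.na(small)))
})

test_that("cluster assignment applies the strict 0.65 retention rule", {
  sigs <- c("C1", "C2", "C5")
  corr <- matrix(0, nrow = 6, ncol = 3,
                 dimnames = list(
                   c("az@0.1@M", "az@10@M",
                     "amb@0.1@M", "amb@10@M",
                     "weak@0.1@M", "weak@10@M"), sigs))
  corr["az@10@M", "C2"] <- 0.8         # one concentration is enough
  corr["amb@0.1@M", "C1"] <- 0.70      # two signatures across concentrations
  corr["amb@10@M", "C5"] <- 0.66
  corr["weak@10@M", "C2"] <- 0.64      # below threshold everywhere
  class(corr) <- c("correlation_table", class(matrix()))
  res <- assign_clusters(corr, threshold = 0.65)
  az <- res[res$chemical_id == "az", ]
  expect_equal(az$status, "classified")
  expect_equal(az$signature, "C2")
  supp <- attr(res, "supporting")$az
  expect_equal(supp$concentration_uM, 10)
  amb <- res[res$chemical_id == "amb", ]
  expect_equal(amb$status, "unclassified_ambiguous")
  expect_equal(amb$candidates, "C1,C5")
  expect_equal(res$status[res$chemical_id == "weak"], "unclassified_low")
  # boundary: exactly 0.65 is NOT above the threshold
  corr["weak@10@M", "C2"] <- 0.65
  res2 <- assign_clusters(corr, threshold = 0.65)
  expect_equal(res2$status[res2$chemical_id == "weak"], "unclassified_low")
  # degenerate thresholds
  expect_true(all(assign_clusters(corr, threshold = 1)$status !=
                    "classified"))
  expect_true(all(assign_clusters(corr, threshold = -1)$n_supporting > 0))
})

test_that("hierarchical clustering merges identical columns first, deterministically", {
  set.seed(4)
  base <- rnorm(10)
  x <- cbind(a = base, b = base, c = rnorm(10))
  rownames(x) <- paste0("g", 1:10)
  nm <- raslscreen:::new_normalized_matrix(x, "centered", "gene")
  hc <- hierarchical_cluster(nm)
  # the identical pair merges at height 0 before anything else
  expect_equal(hc$height[1], 0)
  merged_first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(merged_first, c("a", "b"))
  expect_error(hierarchical_cluster(nm[, 1, drop = FALSE]), ">= 2 columns")
  nw <- as_newick(hc)
  expect_match(nw, "^\\(")
  expect_match(nw, "a")
})

test_that("conditions sharing a ground-truth template co-cluster (ARI >= 0.8)", {
  scr <- recovery_screen(seed = 17, n_per_template = 4, n_null = 0,
                         n_replicates = 2, well_fail_prob = 0,
                         probe_fail_prob = 0)
  qc <- qc_screen(scr$sim$counts, scr$panel)
  norm <- normalize_screen(qc$counts, scr$panel, scr$design)
  ctr <- average_sexes(norm$centered)
  # active conditions only: flat-dose chemicals at every concentration
  meta <- raslscreen:::parse_condition_labels(colnames(ctr))
  tpl <- scr$sim$truth$chemical$template[
    match(meta$chemical_id, scr$sim$truth$chemical$chemical_id)]
  keep <- !is.na(tpl) & tpl != "null" &
    (meta$concentration_uM == 10 | tpl %in% c("C1", "C2", "C5"))
  keep <- keep & !(meta$chemical_id %in% c("thresh_c2") &
                     meta$concentration_uM < 10)
  hc <- hierarchical_cluster(ctr[, keep, drop = FALSE])
  k <- length(unique(tpl[keep]))
  cut <- cutree(hc, k = k)
  truth_lab <- tpl[keep][match(names(cut), colnames(ctr)[keep])]
  ari <- mclust::adjustedRandIndex(cut, truth_lab)
  expect_gte(ari, 0.8)
})

test_that("cross-platform concordance reproduces the closed-form r and p", {
  a <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), paste0("g", 1:10))
  expect_equal(cross_platform_concordance(a, a)$r, 1)
  b <- a
  b["g5"] <- -b["g5"]
  cc <- cross_platform_concordance(a, b)
  # hand-coded formula oracle
  x <- as.numeric(a); y <- as.numeric(b)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc$r, r_oracle)
  t_or <- r_oracle * sqrt(8) / sqrt(1 - r_oracle^2)
  expect_equal(cc$p_value, 2 * pt(abs(t_or), df = 8, lower.tail = FALSE))
  expect_equal(cc$n_genes, 10)
  disjoint <- setNames(1:5, paste0("h", 1:5))
  expect_error(cross_platform_concordance(a, disjoint), ">= 3 shared genes")
})
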