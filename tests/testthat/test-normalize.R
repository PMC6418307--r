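test_that("control log2 ratios follow the closed form and average to zero", {
  panel <- tiny_panel()
  m <- matrix(0L, nrow = 1, ncol = nrow(panel),
              dimnames = list("w1", panel$probe_id))
  # control-probe counts after +1 pseudocount: 2, 8, 4, 16 -> geomean 2^2.5
  m["w1", c("Ascl3_p1", "Psmd4_p1", "Sdha_p1", "Tbp_p1")] <-
    c(1L, 7L, 3L, 15L)
  m["w1", "g1_p1"] <- 31L  # (31+1)/2^2.5 -> log2 = 5 - 2.5
  norm <- log_ratio_normalize(m, panel)
  expect_equal(norm[c("Ascl3_p1", "Psmd4_p1", "Sdha_p1", "Tbp_p1"), "w1"],
               c(Ascl3_p1 = -1.5, Psmd4_p1 = 0.5, Sdha_p1 = -0.5,
                 Tbp_p1 = 1.5))
  expect_equal(norm["g1_p1", "w1"], 2.5)
  expect_equal(mean(norm[c("Ascl3_p1", "Psmd4_p1", "Sdha_p1", "Tbp_p1"),
                         "w1"]), 0)
})

test_that("equal counts across a well give all-zero log ratios", {
  panel <- tiny_panel()
  m <- matrix(7L, nrow = 2, ncol = nrow(panel),
              dimnames = list(c("w1", "w2"), panel$probe_id))
  norm <- log_ratio_normalize(m, panel)
  expect_true(all(norm == 0))
})

test_that("log-ratio normalization matches the brute-force oracle to 1e-12", {
  panel <- tiny_panel()
  for (seed in 1:20) {
    m <- rand_counts(6, nrow(panel), lambda = 40, seed = seed,
                     probes = panel$probe_id)
    norm <- log_ratio_normalize(m, panel)
    oracle <- oracle_log_ratio(m, panel)
    expect_lt(max(abs(norm[, ] - oracle[rownames(norm), colnames(norm)])),
              1e-12)
    # control-probe mean is exactly zero per well
    ctrl <- panel$probe_id[panel$role == "control"]
    expect_lt(max(abs(colMeans(norm[ctrl, ]))), 1e-12)
  }
})

test_that("a missing control gene is a hard error", {
  panel <- tiny_panel()
  m <- rand_counts(3, nrow(panel), seed = 1, probes = panel$probe_id)
  expect_error(log_ratio_normalize(m[, setdiff(colnames(m), "Sdha_p1")],
                                   panel),
               "control gene.*Sdha")
})

test_that("probes collapse to gene medians", {
  panel <- tiny_panel()
  v <- matrix(0, nrow = nrow(panel), ncol = 2,
              dimnames = list(panel$probe_id, c("w1", "w2")))
  v[c("g1_p1", "g1_p2", "g1_p3"), "w1"] <- c(1, 2, 9)
  v["Ascl3_p1", "w1"] <- 4.4
  nm <- raslscreen:::new_normalized_matrix(v, "well", "probe")
  g <- collapse_probes(nm, panel)
  expect_equal(g["g1", "w1"], 2)        # odd-count median
  expect_equal(g["Ascl3", "w1"], 4.4)   # single probe passes through
  # groupby-median oracle on random values
  set.seed(8)
  v[] <- rnorm(length(v))
  g <- collapse_probes(raslscreen:::new_normalized_matrix(v, "well", "probe"),
                       panel)
  for (gn in rownames(g)) {
    probes <- panel$probe_id[panel$gene == gn]
    for (w in colnames(g))
      expect_equal(g[gn, w], median(v[probes, w]))
  }
})

test_that("median polish is exact on additive matrices and constants", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2),(3,4): perfectly additive
  mp <- median_polish(x, output = "residual")
  expect_true(all(mp[, ] == 0))
  expect_equal(unname(attr(mp, "col_effects")), c(-0.5, 0.5))
  expect_lte(attr(mp, "iterations"), 2)
  # residual + row effect keeps gene-relative structure; overall and
  # column effects are gone (rows 1,2 and 3,4 sit at -1 and +1)
  mp2 <- median_polish(x)
  expect_equal(unname(mp2[, ]), matrix(c(-1, 1, -1, 1), 2, 2))

  const <- matrix(5, 3, 4)
  mpc <- median_polish(const, output = "residual")
  expect_true(all(mpc[, ] == 0))
  expect_equal(unname(attr(mpc, "overall")), 5)
})

test_that("median polish matches an independently coded sweep oracle on random 5x7 matrices", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- matrix(rnorm(35), 5, 7)
    mp <- median_polish(x, output = "residual", max_iter = 20, tol = 1e-6)
    or <- oracle_polish(x, max_iter = 20, tol = 1e-6)
    expect_lt(max(abs(mp[, ] - or$residuals)), 1e-12)
    # sweep-by-sweep agreement at the first and second sweeps
    mp1 <- median_polish(x, output = "residual", max_iter = 1)
    expect_lt(max(abs(mp1[, ] - or$snapshots[[1]])), 1e-12)
    if (length(or$snapshots) >= 2) {
      mp2 <- median_polish(x, output = "residual", max_iter = 2)
      expect_lt(max(abs(mp2[, ] - or$snapshots[[2]])), 1e-12)
    }
    # residual row/column medians vanish within tolerance
    expect_lt(max(abs(apply(mp[, ], 1, median))), 1e-6)
    expect_lt(max(abs(apply(mp[, ], 2, median))), 1e-6)
  }
})

test_that("median polish agrees with stats::medpolish on converged matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(35), 5, 7)
    mp <- median_polish(x, output = "residual", max_iter = 200, tol = 1e-10)
    ref <- stats::medpolish(x, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
    expect_lt(max(abs(mp[, ] - ref$residuals)), 1e-4)
  }
})

test_that("median polish rejects non-finite input naming the cell", {
  x <- matrix(1, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  x["gB", "s1"] <- NA
  expect_error(median_polish(x), "gB.*s1")
})

test_that("replicates collapse to per-condition medians with labelled columns", {
  panel <- tiny_panel()
  design <- make_design("drugA", n_replicates = 3, sexes = "M",
                        concentrations = 10, plate_size = 96, seed = 2)
  wells <- design_well_ids(design)[design$chemical_id == "drugA"]
  v <- matrix(0, nrow = 2, ncol = 3,
              dimnames = list(c("g1", "g2"), wells))
  v["g1", ] <- c(0.1, 0.5, 0.9)
  nm <- raslscreen:::new_normalized_matrix(v, "well", "gene")
  cond <- collapse_replicates(nm, design)
  expect_equal(cond["g1", "drugA@10@M"], 0.5)
  # a condition reduced to one well passes that well through
  cond1 <- collapse_replicates(
    raslscreen:::new_normalized_matrix(v[, 1, drop = FALSE], "well", "gene"),
    design)
  expect_equal(cond1["g1", "drugA@10@M"], 0.1)
  expect_error(collapse_replicates(
    raslscreen:::new_normalized_matrix(
      matrix(0, 1, 1, dimnames = list("g1", "nosuch:A01")), "well", "gene"),
    design), "absent from design")
})

test_that("median centering zeroes row medians and separates sex markers", {
  v <- matrix(c(1, 2, 3,
                5, 5, 5,
                2, 0, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "Xist", "g2"),
                              c("a@1@M", "b@1@M", "c@1@M")))
  nm <- raslscreen:::new_normalized_matrix(v, "condition", "gene")
  ctr <- median_center(nm)
  expect_equal(unname(ctr["g1", ]), c(-1, 0, 1))
  expect_false("Xist" %in% rownames(ctr))
  expect_equal(attr(ctr, "sex_marker_values")["Xist", "a@1@M"], 5)
  # idempotent on centered input
  ctr2 <- median_center(ctr)
  expect_equal(ctr2[, ], ctr[, ])
  # property: every row median is 0 to 1e-12 on random inputs
  set.seed(3)
  r <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  rc <- median_center(raslscreen:::new_normalized_matrix(r, "condition", "gene"))
  expect_lt(max(abs(apply(rc[, ], 1, median))), 1e-12)
})

test_that("log-ratio values are invariant to per-well library scaling", {
  panel <- tiny_panel()
  m <- rand_counts(4, nrow(panel), lambda = 5000, seed = 5,
                   probes = panel$probe_id)
  m2 <- m
  m2[2, ] <- m2[2, ] * 8L
  n1 <- log_ratio_normalize(m, panel)
  n2 <- log_ratio_normalize(m2, panel)
  # exact up to the pseudocount, negligible at these depths
  expect_lt(max(abs(n1[, 2] - n2[, 2])), 0.005)
  expect_equal(n1[, -2], n2[, -2])
})

test_that("sexes average into chemical-by-concentration columns", {
  v <- matrix(c(1, 3, 2, 2), nrow = 1,
              dimnames = list("g1", c("a@1@M", "a@1@F", "b@1@M", "b@1@F")))
  nm <- raslscreen:::new_normalized_matrix(v, "condition", "gene")
  av <- average_sexes(nm)
  expect_equal(colnames(av), c("a@1", "b@1"))
  expect_equal(unname(av["g1", ]), c(2, 2))
})
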