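test_that("well filter is strict: a well at exactly the threshold is dropped", {
  m <- matrix(c(499L, 500L, 501L), nrow = 3, ncol = 1,
              dimnames = list(c("w1", "w2", "w3"), "pA"))
  res <- filter_wells(m, min_total = 500)
  expect_equal(rownames(res$counts), "w3")
  expect_equal(res$report$pass, c(FALSE, FALSE, TRUE))
  # >= variant keeps the boundary well
  res_ge <- filter_wells(m, min_total = 500, strict = FALSE)
  expect_setequal(rownames(res_ge$counts), c("w2", "w3"))
})

test_that("probe filter is strict and protects control genes", {
  m <- matrix(c(1000L, 1001L), nrow = 1, ncol = 2,
              dimnames = list("w1", c("p1", "p2")))
  res <- filter_probes(m, min_total = 1000)
  expect_equal(colnames(res$counts), "p2")

  panel <- tiny_panel()
  counts <- matrix(2000L, nrow = 2, ncol = nrow(panel),
                   dimnames = list(c("w1", "w2"), panel$probe_id))
  counts[, "Tbp_p1"] <- 0L
  expect_error(filter_probes(counts, panel), "control gene Tbp")
})

test_that("an all-zero matrix retains no wells, with a warning not an error", {
  m <- matrix(0L, 2, 2, dimnames = list(c("w1", "w2"), c("p1", "p2")))
  expect_warning(res <- filter_wells(m), "no wells pass")
  expect_equal(nrow(res$counts), 0)
})

test_that("filters agree with brute-force enumeration on random matrices", {
  for (seed in 1:100) {
    m <- rand_counts(8, 6, lambda = 95, seed = seed)
    wf <- filter_wells(m, min_total = 500)
    keep <- character(0)
    for (w in rownames(m)) if (sum(m[w, ]) > 500) keep <- c(keep, w)
    expect_identical(rownames(wf$counts), keep)

    pf <- filter_probes(m, min_total = 700)
    keep_p <- character(0)
    for (p in colnames(m)) if (sum(m[, p]) > 700) keep_p <- c(keep_p, p)
    expect_identical(colnames(pf$counts), keep_p)
  }
})

test_that("filters are idempotent and conserve well counts", {
  m <- rand_counts(20, 10, lambda = 80, seed = 7)
  wf <- filter_wells(m)
  wf2 <- filter_wells(wf$counts)
  expect_identical(wf2$counts, wf$counts)
  pf <- filter_probes(m, min_total = 1500)
  pf2 <- filter_probes(pf$counts, min_total = 1500)
  expect_identical(pf2$counts, pf$counts)
  expect_equal(sum(wf$report$pass) + sum(!wf$report$pass), nrow(m))
})

test_that("luciferase fraction follows its definition and display scale", {
  panel <- tiny_panel()
  m <- matrix(0L, nrow = 3, ncol = nrow(panel),
              dimnames = list(c("w1", "w2", "w3"), panel$probe_id))
  m["w1", ] <- 83L   # 10 probes; set spike share explicitly below
  m["w1", "Luc_p1"] <- 250L
  m["w1", setdiff(colnames(m), "Luc_p1")] <- 750L %/% 9L
  m["w1", "g1_p1"] <- m["w1", "g1_p1"] + (750L - 9L * (750L %/% 9L))
  expect_equal(sum(m["w1", ]), 1000L)
  m["w2", "g1_p1"] <- 500L  # zero spike reads
  frac <- luciferase_fraction(m, panel)
  expect_equal(unname(frac["w1"]), 0.25)
  expect_equal(unname(frac["w2"]), 0)
  expect_true(is.na(frac["w3"]))  # 0/0 undefined
  expect_error(luciferase_fraction(m[, 1:3], panel), "no spike probes")
})

test_that("qc_screen separates spikes, filters on full totals, and accounts for drops", {
  scr <- recovery_screen(seed = 13, n_per_template = 1, n_null = 2,
                         n_replicates = 1, well_fail_prob = 0.15)
  qc <- qc_screen(scr$sim$counts, scr$panel)
  # spike probes never in the analysis matrix
  expect_length(intersect(colnames(qc$counts),
                          scr$panel$probe_id[scr$panel$role == "spike"]), 0)
  # conservation
  expect_equal(qc$report$n_wells_dropped + sum(qc$report$wells$pass),
               nrow(scr$sim$counts))
  # well totals were computed on the full matrix including spikes
  expect_equal(qc$report$wells$total_reads,
               unname(rowSums(scr$sim$counts)[qc$report$wells$well_id]))
  # probe totals summed across all wells, before well filtering
  cellular <- scr$sim$counts[, scr$panel$probe_id[scr$panel$role != "spike"]]
  expect_equal(qc$report$probes$total_reads,
               unname(colSums(cellular)[qc$report$probes$probe_id]))
  # failed wells fall below the bar
  failed <- scr$sim$truth$well$well_id[scr$sim$truth$well$failed]
  expect_true(all(!qc$report$wells$pass[qc$report$wells$well_id %in% failed]))
})
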