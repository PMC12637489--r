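test_that("the FPI curve enumerates observed FP ratios with exact fractions", {
  fp <- compartment_list("ER_membrane", c("F1", "F2", "F3", "F4"))
  et <- make_enrichment(c(F1 = 1, F2 = 2, F3 = 3, F4 = 4, X1 = 9))
  curve <- fpi_curve(et, fp)
  expect_equal(curve$points$cutoff, c(1, 2, 3, 4))
  expect_equal(curve$points$fpi, c(0.75, 0.5, 0.25, 0))
  expect_equal(curve$n_fp_observed, 4)

  # degenerate: all FP ratios equal -> a single point at (v, 0)
  et <- make_enrichment(c(F1 = 0.3, F2 = 0.3, F3 = 0.3))
  curve <- fpi_curve(et, compartment_list("x", c("F1", "F2", "F3")))
  expect_equal(curve$points, data.frame(cutoff = 0.3, fpi = 0))

  # empty intersection errors and names the list
  et <- make_enrichment(c(P1 = 1))
  expect_error(fpi_curve(et, compartment_list("cell_membrane", "Q1")),
               "cell_membrane")
})

test_that("FPI curves are non-increasing step functions on random input", {
  set.seed(20)
  for (i in 1:25) {
    n <- sample(3:150, 1)
    vals <- round(rnorm(n), sample(0:2, 1))  # rounding plants heavy ties
    acc <- sprintf("F%03d", seq_len(n))
    curve <- fpi_curve(make_enrichment(setNames(vals, acc)),
                       compartment_list("fp", acc))
    expect_true(all(diff(curve$points$cutoff) > 0))
    expect_true(all(diff(curve$points$fpi) <= 0))
    expect_equal(tail(curve$points$fpi, 1), 0)
    # fpi at each cutoff equals the brute-force strictly-above fraction
    brute <- vapply(curve$points$cutoff, function(c) mean(vals > c), numeric(1))
    expect_equal(curve$points$fpi, brute)
  }
})

test_that("cutoff selection reproduces the 3-percent-above construction", {
  # 100 distinct FP ratios 0.01..1.00 at target 0.03: cutoff 0.97, 3 above
  acc <- sprintf("F%03d", 1:100)
  curve <- fpi_curve(make_enrichment(setNames(seq(0.01, 1, 0.01), acc)),
                     compartment_list("ER_membrane", acc))
  res <- cutoff_at_fpi(curve, 0.03)
  expect_equal(res$cutoff, 0.97)
  expect_equal(res$n_fp_above, 3L)
  expect_equal(res$achieved_fpi, 0.03)

  # n = 10 distinct at target 0.05: floor(0.5) = 0 exceedances allowed,
  # cutoff is the maximum observed FP ratio
  acc <- sprintf("F%02d", 1:10)
  vals <- setNames(sort(rnorm(10)), acc)
  curve <- fpi_curve(make_enrichment(vals), compartment_list("fp", acc))
  res <- cutoff_at_fpi(curve, 0.05)
  expect_equal(res$cutoff, max(vals))
  expect_equal(res$n_fp_above, 0L)

  expect_error(cutoff_at_fpi(curve, 0), "\\(0, 1\\)")
  expect_error(cutoff_at_fpi(curve, 1), "\\(0, 1\\)")
})

test_that("the FPI guarantee holds under randomized input with heavy ties", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    vals <- round(rnorm(n, sd = sample(c(0.1, 1), 1)), sample(0:1, 1))
    acc <- sprintf("F%03d", seq_len(n))
    curve <- fpi_curve(make_enrichment(setNames(vals, acc)),
                       compartment_list("fp", acc))
    target <- runif(1, 0.01, 0.3)
    res <- cutoff_at_fpi(curve, target)
    # defining contract: achieved FPI never exceeds the target
    expect_lte(res$achieved_fpi, target)
    expect_equal(res$achieved_fpi, mean(vals > res$cutoff))
    expect_equal(res$n_fp_above, sum(vals > res$cutoff))
  }
})

test_that("cutoff_at_fpi agrees with exhaustive minimal-cutoff search", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    vals <- round(rnorm(n), sample(0:2, 1))
    acc <- sprintf("F%03d", seq_len(n))
    curve <- fpi_curve(make_enrichment(setNames(vals, acc)),
                       compartment_list("fp", acc))
    target <- runif(1, 0.005, 0.2)
    expect_equal(cutoff_at_fpi(curve, target)$cutoff,
                 brute_force_cutoff(vals, target))
  }
})

test_that("stricter targets give higher cutoffs and nested survivor sets", {
  set.seed(32)
  acc <- sprintf("F%03d", 1:120)
  vals <- setNames(rnorm(120), acc)
  all_acc <- sprintf("P%03d", 1:500)
  table_vals <- setNames(rnorm(500, 1), all_acc)
  et <- make_enrichment(c(vals, table_vals))
  curve <- fpi_curve(et, compartment_list("fp", acc))
  strict <- cutoff_at_fpi(curve, 0.03)
  loose <- cutoff_at_fpi(curve, 0.05)
  expect_gte(strict$cutoff, loose$cutoff)
  s_strict <- apply_filter(et, strict)
  s_loose <- apply_filter(et, loose)
  expect_true(all(s_strict %in% s_loose))
})

test_that("apply_filter selects strict exceedances only", {
  et <- make_enrichment(c(P1 = 5, P2 = -1))
  cut <- structure(list(cutoff = 0.5), class = "cutoff_result")
  expect_equal(apply_filter(et, cut), "P1")
  cut$cutoff <- 10
  expect_length(apply_filter(et, cut), 0)
  # boundary value is excluded (strictly greater than)
  et <- make_enrichment(c(P1 = 0.5))
  cut$cutoff <- 0.5
  expect_length(apply_filter(et, cut), 0)
  # enumeration oracle
  set.seed(33)
  vals <- setNames(rnorm(300), sprintf("P%03d", 1:300))
  cut$cutoff <- 0.2
  expect_setequal(apply_filter(make_enrichment(vals), cut),
                  names(vals)[vals > 0.2])
})

test_that("replicate intersection and ranking build the final proteome", {
  vals <- c(A = 3, B = 2.5, C = 2, BAIT = 6, D = 0.1)
  ratios <- list(
    vs_no_ligase.rep1 = make_enrichment(vals, "vs_no_ligase", "rep1"),
    vs_no_ligase.rep2 = make_enrichment(vals, "vs_no_ligase", "rep2"),
    vs_spatial_control.rep1 = make_enrichment(vals, "vs_spatial_control", "rep1"),
    vs_spatial_control.rep2 = make_enrichment(vals, "vs_spatial_control", "rep2"))
  pass <- list(vs_no_ligase.rep1 = c("A", "B", "BAIT"),
               vs_no_ligase.rep2 = c("B", "C", "BAIT"),
               vs_spatial_control.rep1 = c("A", "B", "C", "BAIT"),
               vs_spatial_control.rep2 = c("B", "C", "BAIT"))
  prot <- build_proteome(pass, ratios, "BAIT")
  # rep1 survivors {A,B,BAIT} & rep2 survivors {B,C,BAIT} -> {B,BAIT}
  expect_setequal(prot$entries$accession, c("B", "BAIT"))
  expect_equal(prot$entries$accession[prot$entries$rank == 1], "BAIT")
  expect_equal(prot$entries$mean_enrichment,
               sort(c(6, 2.5), decreasing = TRUE))
  expect_true(prot$entries$is_bait[1])

  # empty intersection: empty proteome, provenance retained, bait warning
  pass$vs_no_ligase.rep2 <- character(0)
  expect_warning(empty <- build_proteome(pass, ratios, "BAIT",
                                         provenance = list(note = "x")),
                 "did not pass")
  expect_equal(nrow(empty$entries), 0)
  expect_equal(empty$provenance$note, "x")
  expect_equal(empty$provenance$rep1_survivors, 3)
})

test_that("fold reduction is plain division with an infinite-reduction flag", {
  expect_equal(fold_reduction(5000, 100), 50)
  expect_equal(fold_reduction(100, 100), 1)
  expect_warning(expect_equal(fold_reduction(10, 0), Inf), "infinite")
  set.seed(34)
  for (i in 1:10) {
    b <- sample(1e5, 1); a <- sample(b, 1)
    expect_equal(fold_reduction(b, a), b / a)
  }
})

test_that("on synthetic data the bait ranks first and sets are nested", {
  sim <- simulate_experiment(sim_config(seed = 7))
  res <- suppressMessages(run_pipeline(sim$quant, sim$er_list, sim$cm_list,
                                       bait = sim$bait))
  entries <- res$proteome$entries
  expect_equal(entries$accession[entries$rank == 1], sim$bait)
  # final proteome is contained in each replicate's survivors, which are
  # contained in the peptide-filtered input
  kept <- filter_by_peptides(sim$quant, 2)$accession
  expect_true(all(entries$accession %in% kept))
  for (k in names(res$cutoffs)) {
    surv <- apply_filter(res$ratios[[k]], res$cutoffs[[k]])
    expect_true(all(entries$accession %in% surv))
    expect_true(all(surv %in% kept))
  }
})
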