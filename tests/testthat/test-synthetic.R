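test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_background = -1), "non-negative")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(replicate_rho = 1.2), "replicate_rho")
})

test_that("class bookkeeping is exact", {
  cfg <- sim_config(n_background = 100, n_true_proximal = 10, n_er_fp = 20,
                    n_cm_fp = 20, n_contaminant = 5, seed = 7)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$quant), 156)  # 155 simulated + the bait
  counts <- table(sim$truth$class)
  expect_equal(unname(counts[["bait"]]), 1)
  expect_equal(unname(counts[["true_proximal"]]), 10)
  expect_equal(unname(counts[["background"]]), 100)
  expect_equal(unname(counts[["er_fp"]]), 20)
  expect_equal(unname(counts[["cm_fp"]]), 20)
  expect_equal(unname(counts[["contaminant"]]), 5)
  # compartment lists contain exactly the simulated FP accessions
  expect_setequal(sim$er_list$accessions,
                  sim$truth$accession[sim$truth$class == "er_fp"])
  expect_setequal(sim$cm_list$accessions,
                  sim$truth$accession[sim$truth$class == "cm_fp"])
  # classes partition all accessions, accessions unique
  expect_false(any(duplicated(sim$truth$accession)))
  expect_setequal(sim$truth$accession, sim$quant$accession)
})

test_that("a fixed seed is bit-identical and a new seed is not", {
  cfg <- sim_config(n_background = 100, n_true_proximal = 10, n_er_fp = 20,
                    n_cm_fp = 20, n_contaminant = 5, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$quant, b$quant)
  expect_identical(a$truth, b$truth)
  cfg8 <- sim_config(n_background = 100, n_true_proximal = 10, n_er_fp = 20,
                     n_cm_fp = 20, n_contaminant = 5, seed = 8)
  c <- simulate_experiment(cfg8)
  expect_false(identical(a$quant[["133N"]], c$quant[["133N"]]))
})

test_that("null-effect, vanishing-noise limit gives zero ratios between labeled channels", {
  cfg <- sim_config(n_background = 50, n_true_proximal = 5, n_er_fp = 10,
                    n_cm_fp = 10, n_contaminant = 0, bait_effect = 0,
                    bait_vs_noligase_effect = 0, bait_self_effect = 0,
                    noise_sd = 1e-9, seed = 1)
  sim <- simulate_experiment(cfg)
  ratios <- compute_enrichment(sim$quant)
  for (r in ratios) expect_true(all(abs(r$values) < 1e-6))
})

test_that("expected_ratio returns the generative means and rejects unknowns", {
  cfg <- sim_config(bait_effect = 2.0, bait_vs_noligase_effect = 1.5)
  expect_equal(expected_ratio(cfg, "background", "vs_spatial_control"), 0)
  expect_equal(expected_ratio(cfg, "true_proximal", "vs_spatial_control"), 2.0)
  expect_equal(expected_ratio(cfg, "true_proximal", "vs_no_ligase"), 3.5)
  expect_equal(expected_ratio(cfg, "er_fp", "vs_no_ligase"), 1.5)
  expect_equal(expected_ratio(cfg, "contaminant", "vs_no_ligase"), 0)
  expect_equal(expected_ratio(cfg, "bait", "vs_spatial_control"),
               cfg$bait_self_effect)
  expect_error(expected_ratio(cfg, "nucleolus", "vs_no_ligase"), "class")
  expect_error(expected_ratio(cfg, "background", "sideways"), "axis")
})

test_that("empirical class means converge to the closed-form expected ratios", {
  # Monte-Carlo check at 10,000 true-proximal draws, noise_sd = 0.3:
  # mean log2 ratio must match the closed form within +/- 0.02
  cfg <- sim_config(n_background = 10000, n_true_proximal = 10000,
                    n_er_fp = 0, n_cm_fp = 0, n_contaminant = 0,
                    noise_sd = 0.3, seed = 99)
  sim <- simulate_experiment(cfg)
  ratios <- compute_enrichment(sim$quant)
  for (cls in c("true_proximal", "background")) {
    acc <- sim$truth$accession[sim$truth$class == cls]
    for (axis in c("vs_no_ligase", "vs_spatial_control")) {
      emp <- mean(ratios[[paste0(axis, ".rep1")]]$values[acc])
      expect_equal(emp, expected_ratio(cfg, cls, axis), tolerance = 0.02,
                   label = paste(cls, axis))
    }
  }
})

test_that("law of large numbers: per-class means within 3 sd / sqrt(n)", {
  cfg <- sim_config(n_background = 5000, n_true_proximal = 5000,
                    n_er_fp = 0, n_cm_fp = 0, n_contaminant = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  ratios <- compute_enrichment(sim$quant)
  for (cls in c("true_proximal", "background")) {
    acc <- sim$truth$accession[sim$truth$class == cls]
    for (axis in c("vs_no_ligase", "vs_spatial_control")) {
      v <- ratios[[paste0(axis, ".rep1")]]$values[acc]
      tol <- 3 * sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - expected_ratio(cfg, cls, axis)), tol)
    }
  }
})

test_that("replicate correlation increases with replicate_rho", {
  cors <- vapply(c(0.0, 0.5, 0.95), function(rho) {
    cfg <- sim_config(n_background = 5000, n_true_proximal = 0, n_er_fp = 0,
                      n_cm_fp = 0, n_contaminant = 0, replicate_rho = rho,
                      seed = 21)
    sim <- simulate_experiment(cfg)
    ratios <- compute_enrichment(sim$quant)
    shared <- intersect(names(ratios[["vs_spatial_control.rep1"]]$values),
                        names(ratios[["vs_spatial_control.rep2"]]$values))
    cor(ratios[["vs_spatial_control.rep1"]]$values[shared],
        ratios[["vs_spatial_control.rep2"]]$values[shared])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("synthetic GO annotations are deterministic and lower-cased", {
  acc <- sprintf("P%03d", 1:50)
  a <- simulate_go_annotations(acc, seed = 4)
  b <- simulate_go_annotations(acc, seed = 4)
  expect_identical(a, b)
  expect_true(all(vapply(unlist(a), function(t) t == tolower(t), logical(1))))
})
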