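test_that("the sign-based empirical p-value follows the stated rule", {
  p <- empirical_p(c(-1, 2, 3, 4))  # mean 2 > 0, q = 1/4
  expect_equal(as.numeric(p), 0.5)
  expect_equal(attr(p, "uncapped"), 0.5)
  expect_equal(as.numeric(empirical_p(c(0.2, 0.5, 1.1))), 0)
  # symmetric about 0 with mean <= 0 and q = 1/2
  expect_equal(as.numeric(empirical_p(c(-2, -1, 1, 2))), 1)
  # the raw formula can exceed 1: mean <= 0 with no negative estimates
  p2 <- empirical_p(c(0, 0))
  expect_equal(as.numeric(p2), 1)
  expect_equal(attr(p2, "uncapped"), 2)
  expect_error(empirical_p(numeric(0)), "non-empty")
  expect_error(empirical_p(c(1, NA)), "NA")
})

test_that("replicate summaries average on the log scale", {
  sc <- scenario_config(maf = 0.25, disease_scale = 0.005)
  est <- function(b, conv = TRUE)
    irrbias:::assoc_estimate(b, 0.1, "classical", conv, 10, 50)
  s <- summarize_replicates(sc, "classical", list(est(log(2)), est(log(8))))
  expect_equal(s$mean_estimate, 4)  # geometric mean under log averaging
  expect_equal(s$mean_log_estimate, mean(log(c(2, 8))))
  s_resp <- summarize_replicates(sc, "classical",
                                 list(est(log(2)), est(log(8))),
                                 avg_scale = "response")
  expect_equal(s_resp$mean_estimate, 5)  # arithmetic mean of 2 and 8
  # single estimate, and degenerate bookkeeping
  s1 <- summarize_replicates(sc, "classical", list(est(0.3)))
  expect_equal(s1$mean_log_estimate, 0.3)
  s2 <- summarize_replicates(sc, "classical",
                             list(est(0.3), NULL, est(99, conv = FALSE)))
  expect_identical(s2$n_used, 1L)
  expect_identical(s2$n_degenerate, 2L)
  s3 <- summarize_replicates(sc, "classical", list(NULL))
  expect_true(is.na(s3$mean_log_estimate))
})

test_that("replicate runs are deterministic in (scenario, R, seed)", {
  sc <- scenario_config(maf = 0.25, irr_disease = 1.5, n_individuals = 400,
                        disease_scale = 0.005, rarity_target = NA)
  r1 <- run_replicates(sc, R = 2, base_seed = 5)
  r2 <- run_replicates(sc, R = 2, base_seed = 5)
  expect_identical(r1, r2)
  expect_identical(names(r1), c("classical", "classical_age_adjusted",
                                "incidence_density"))
  expect_identical(lengths(r1), c(classical = 2L,
                                  classical_age_adjusted = 2L,
                                  incidence_density = 2L))
  r3 <- run_replicates(sc, R = 1, base_seed = 6,
                       designs = "incidence_density")
  expect_identical(length(r3$incidence_density), 1L)
  expect_s3_class(r3$incidence_density[[1]], "assoc_estimate")
  # a different base seed changes the estimates
  r4 <- run_replicates(sc, R = 2, base_seed = 6)
  expect_false(identical(r1$classical[[1]]$log_estimate,
                         r4$classical[[1]]$log_estimate))
})

test_that("the analytic odds-ratio oracle has the expected structure", {
  null_sc <- scenario_config(maf = 0.25, irr_disease = 1, irr_death = 1)
  expect_equal(analytic_or(null_sc), 0, tolerance = 1e-8)
  # no competing-event association and a rare disease: OR ~ IRR
  for (irr in c(1.1, 1.5, 2.0)) {
    sc <- scenario_config(maf = 0.25, irr_disease = irr, irr_death = 1,
                          rarity_target = 0.025)
    expect_lt(abs(analytic_or(sc) - log(irr)), 0.02)
  }
  # protective competing association inflates the common-disease OR
  sc_up <- scenario_config(maf = 0.25, irr_disease = 1.5, irr_death = 0.5,
                           rarity_target = 0.22)
  expect_gt(analytic_or(sc_up), log(1.5))
})

test_that("grid configs are read from YAML with defaults filled in", {
  smoke <- read_grid_config(system.file("config", "smoke.yaml",
                                        package = "irrbias"))
  expect_s3_class(smoke, "grid_config")
  expect_identical(smoke$n_replicates, 10L)
  expect_equal(smoke$disease_baselines[[1]]$mode, 50)
  full <- read_grid_config(system.file("config", "paper_defaults.yaml",
                                       package = "irrbias"))
  expect_identical(length(irrbias:::grid_scenarios(full)), 960L)
  # a partial file falls back to function defaults
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("maf: [0.1]", "n_replicates: 3"), p)
  partial <- read_grid_config(p)
  expect_identical(partial$maf, 0.1)
  expect_identical(partial$n_replicates, 3L)
  expect_equal(partial$death_baseline$mode, 85)
})

test_that("run_grid sweeps, bookkeeps and resumes", {
  g <- grid_config(maf = 0.25, irr_disease = c(1, 1.5), irr_death = 1,
                   disease_baselines = gompertz_baseline(50, 0.1),
                   rarity_targets = 0.22, n_individuals = 400,
                   n_replicates = 3, base_seed = 2,
                   designs = c("classical", "incidence_density"))
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- run_grid(g, out, verbose = FALSE)
  expect_identical(nrow(res), 4L)  # 2 scenarios x 2 designs
  expect_true(all(res$n_used + res$n_degenerate == 3L))
  expect_true(all(c("analytic_log_or", "true_log_irr", "empirical_p",
                    "empirical_p_uncapped") %in% names(res)))
  # resuming over a complete file changes nothing
  res2 <- run_grid(g, out, verbose = FALSE)
  expect_identical(res, res2)
  # a widened grid only appends the missing scenarios
  g2 <- g
  g2$irr_disease <- c(1, 1.5, 2)
  res3 <- run_grid(g2, out, verbose = FALSE)
  expect_identical(nrow(res3), 6L)
  expect_identical(res3[seq_len(4), ], res[seq_len(4), ])
})
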