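test_that("classical sampling follows the 1:ratio subsampling rule", {
  # 10 cases, 80 never-diseased: 80 > 50, so exactly 50 controls
  coh <- make_cohort(genotype = rep(0:1, 45),
                     time = seq(10, 89, length.out = 90),
                     event = rep(c("disease", "death", "censored"),
                                 c(10, 30, 50)))
  set.seed(1)
  d <- sample_classical(coh, ratio = 5)
  expect_identical(attr(d, "n_cases"), 10L)
  expect_identical(attr(d, "n_controls"), 50L)
  expect_false(attr(d, "degenerate"))
  # 10 cases, 30 eligible: all 30 kept
  coh2 <- make_cohort(genotype = rep(0:1, 20),
                      time = seq(10, 89, length.out = 40),
                      event = rep(c("disease", "death", "censored"),
                                  c(10, 15, 15)))
  d2 <- sample_classical(coh2, ratio = 5)
  expect_identical(attr(d2, "n_controls"), 30L)
  # control ages are simulated, case ages are onset ages
  expect_identical(d2$age[d2$is_case == 1], coh2$time[1:10])
  expect_true(all(d2$age >= 0 & d2$age <= 90))
})

test_that("classical sampling flags cohorts without cases as degenerate", {
  coh <- make_cohort(genotype = c(0, 1, 2), time = c(90, 90, 50),
                     event = c("censored", "censored", "death"))
  d <- sample_classical(coh)
  expect_true(attr(d, "degenerate"))
  expect_identical(nrow(d), 0L)
})

test_that("survivors_only restricts eligible controls to the censored", {
  coh <- make_cohort(genotype = rep(0, 6), time = c(40, 50, 60, 90, 90, 90),
                     event = c("disease", "death", "death",
                               "censored", "censored", "censored"))
  d <- sample_classical(coh, survivors_only = TRUE)
  expect_identical(attr(d, "n_controls"), 3L)
  d2 <- sample_classical(coh, survivors_only = FALSE)
  expect_identical(attr(d2, "n_controls"), 5L)
})

test_that("incidence density risk sets match exhaustive recomputation", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    coh <- make_cohort(
      genotype = sample(0:2, n, replace = TRUE),
      time = round(runif(n, 10, 90), 1),  # rounding provokes ties
      event = sample(c("disease", "death", "censored"), n, replace = TRUE))
    coh$time[coh$event == "censored"] <- 90
    m <- sample(2:5, 1)
    d <- sample_incidence_density(coh, m = m)
    cases <- which(coh$event == "disease")
    expected_sets <- 0L
    for (i in cases) {
      elig <- which(coh$time > coh$time[i])  # brute-force risk set
      if (!length(elig)) next
      expected_sets <- expected_sets + 1L
      s <- d[d$set_id == expected_sets, ]
      expect_identical(s$genotype[s$is_case == 1], coh$genotype[i])
      expect_identical(s$match_age[1], coh$time[i])
      expect_identical(nrow(s) - 1L, min(m, length(elig)))
      if (length(elig) <= m) {
        # all eligible controls must be taken, in which case genotype
        # multisets must agree exactly
        expect_identical(sort(s$genotype[s$is_case == 0]),
                         sort(coh$genotype[elig]))
      }
    }
    expect_identical(attr(d, "n_sets"), expected_sets)
    expect_identical(attr(d, "n_dropped"),
                     length(cases) - expected_sets)
  }
})

test_that("risk-set controls are drawn uniformly", {
  # one case at 40 and six eligible controls with genotypes 0,1,2,0,1,2:
  # sampling 5 of 6 uniformly leaves out one individual chosen uniformly,
  # so the left-out genotype is uniform over {0,1,2}
  coh <- make_cohort(genotype = c(1L, rep(0:2, 2)), time = c(40, 51:56),
                     event = c("disease", rep("death", 3),
                               rep("censored", 3)))
  coh$time[5:7] <- 90
  left_out <- integer(3)
  set.seed(8)
  for (i in 1:3000) {
    d <- sample_incidence_density(coh, m = 5)
    expect_identical(nrow(d), 6L)
    picked <- d$genotype[d$is_case == 0]
    expect_identical(length(picked), 5L)
    missing_g <- which(tabulate(picked + 1L, 3L) == 1L) - 1L
    left_out[missing_g + 1L] <- left_out[missing_g + 1L] + 1L
  }
  expect_gt(chisq.test(left_out)$p.value, 0.001)
})

test_that("future cases are eligible controls and sets exclude their own case", {
  coh <- make_cohort(genotype = c(1, 2, 0), time = c(40, 50, 90),
                     event = c("disease", "disease", "censored"))
  set.seed(3)
  d <- sample_incidence_density(coh, m = 5)
  s1 <- d[d$set_id == 1, ]  # case at 40: both others eligible
  expect_setequal(s1$genotype[s1$is_case == 0], c(2, 0))
  s2 <- d[d$set_id == 2, ]  # case at 50: only the censored individual
  expect_identical(s2$genotype[s2$is_case == 0], 0L)
  # a control whose time ties the case onset exactly is excluded
  coh_tie <- make_cohort(genotype = c(1, 0, 0), time = c(40, 40, 90),
                         event = c("disease", "death", "censored"))
  d_tie <- sample_incidence_density(coh_tie, m = 5)
  expect_identical(d_tie$genotype[d_tie$is_case == 0], 0L)
  expect_identical(nrow(d_tie[d_tie$set_id == 1, ]), 2L)
})

test_that("cases with empty risk sets are dropped and counted", {
  coh <- make_cohort(genotype = c(1, 0), time = c(89, 40),
                     event = c("disease", "death"))
  d <- sample_incidence_density(coh, m = 5)
  expect_identical(attr(d, "n_sets"), 0L)
  expect_identical(attr(d, "n_dropped"), 1L)
  expect_true(attr(d, "degenerate"))
})

test_that("sampling leaves the cohort unchanged and is seed-reproducible", {
  sc <- scenario_config(maf = 0.25, n_individuals = 500,
                        disease_scale = 0.005)
  coh <- simulate_cohort(sc, seed = 12)
  snapshot <- coh
  set.seed(99); d1 <- sample_incidence_density(coh)
  set.seed(99); d2 <- sample_incidence_density(coh)
  set.seed(99); c1 <- sample_classical(coh)
  set.seed(99); c2 <- sample_classical(coh)
  expect_identical(d1, d2)
  expect_identical(c1, c2)
  expect_identical(coh, snapshot)
})

test_that("designs round-trip through the tab-separated format", {
  sc <- scenario_config(maf = 0.25, n_individuals = 300,
                        disease_scale = 0.01)
  coh <- simulate_cohort(sc, seed = 6)
  set.seed(1)
  cc <- sample_classical(coh)
  md <- sample_incidence_density(coh)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_design(cc, p1); write_design(md, p2)
  cc_back <- read_design(p1); md_back <- read_design(p2)
  expect_s3_class(cc_back, "case_control")
  expect_s3_class(md_back, "matched_design")
  expect_equal(as.data.frame(cc_back), as.data.frame(cc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.data.frame(md_back), as.data.frame(md), tolerance = 1e-12,
               ignore_attr = TRUE)
})
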