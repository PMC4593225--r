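#' Sign-based empirical p-value over replicate estimates
#'
#' With q the proportion of replicate estimates below 0 and m their mean,
#' the two-sided empirical p-value is `2 q` when `m > 0` and `2 (1 - q)`
#' when `m <= 0`. The raw value can exceed 1; the returned value is capped
#' at 1 and the uncapped value is attached as attribute `"uncapped"`. With
#' R replicates the achievable resolution is 2/R.
#'
#' @param estimates Non-empty numeric vector of replicate log-scale
#'   estimates (no `NA`s).
#' @return The capped p-value, with attribute `"uncapped"`.
#' @examples
#' empirical_p(c(-1, 2, 3, 4))  # 0.5
#' @export
empirical_p <- function(estimates) {
  if (!length(estimates)) stop("'estimates' must be non-empty")
  if (any(is.na(estimates))) stop("'estimates' must not contain NA")
  q <- mean(estimates < 0)
  m <- mean(estimates)
  raw <- if (m > 0) 2 * q else 2 * (1 - q)
  structure(min(1, raw), uncapped = raw)
}

## deterministic replicate seed, kept below 2^31; exact in double arithmetic
replicate_seed <- function(base_seed, scenario_index, r) {
  as.integer(((abs(base_seed) %% 1e6) * 2039 + scenario_index * 104729 +
                r * 7 + 1) %% 2147483629)
}

#' Run replicated cohort simulations and fit both designs
#'
#' For each replicate r = 1..R a fresh cohort is simulated with a seed
#' derived deterministically from `(base_seed, scenario_index, r)`, the
#' requested designs are sampled from it, and the corresponding estimators
#' are fitted. Replicates on which a design is degenerate (no cases) or an
#' estimator fails are recorded as `NULL` / non-converged rather than
#' aborting the loop.
#'
#' @param scenario A [scenario_config()].
#' @param R Number of replicates.
#' @param base_seed Integer base seed.
#' @param designs Character subset of `c("classical",
#'   "classical_age_adjusted", "incidence_density")`.
#' @param scenario_index Integer offset entering the replicate seeds so that
#'   grid cells use disjoint seed streams.
#' @return Named list (one element per design) of lists of
#'   `"assoc_estimate"` objects (`NULL` for degenerate replicates).
#' @export
run_replicates <- function(scenario, R, base_seed,
                           designs = c("classical", "classical_age_adjusted",
                                       "incidence_density"),
                           scenario_index = 0L) {
  stopifnot(inherits(scenario, "scenario_config"), R >= 1)
  designs <- match.arg(designs, several.ok = TRUE)
  scenario <- resolve_scale(scenario)
  out <- lapply(designs, function(d) vector("list", R))
  names(out) <- designs
  classical_wanted <- any(designs %in% c("classical", "classical_age_adjusted"))
  for (r in seq_len(R)) {
    cohort <- simulate_cohort(scenario,
                              replicate_seed(base_seed, scenario_index, r))
    if (classical_wanted) {
      cc <- sample_classical(cohort, ratio = scenario$controls_per_case)
      if (!attr(cc, "degenerate")) {
        if ("classical" %in% designs)
          out$classical[[r]] <- tryCatch(fit_logistic(cc, adjust_age = FALSE),
                                         error = function(e) NULL)
        if ("classical_age_adjusted" %in% designs)
          out$classical_age_adjusted[[r]] <-
            tryCatch(fit_logistic(cc, adjust_age = TRUE),
                     error = function(e) NULL)
      }
    }
    if ("incidence_density" %in% designs) {
      md <- sample_incidence_density(cohort, m = scenario$controls_per_case)
      if (!attr(md, "degenerate"))
        out$incidence_density[[r]] <-
          tryCatch(fit_conditional_logistic(md), error = function(e) NULL)
    }
  }
  out
}

#' Summarize replicate estimates for one scenario and design
#'
#' Averages the usable (converged, finite) replicate estimates on the log
#' scale — both fitted models return log ratios — and exponentiates the mean
#' for reporting; set `avg_scale = "response"` to average the exponentiated
#' estimates arithmetically instead. The sign-based [empirical_p()] is
#' computed from the same usable log estimates.
#'
#' @param scenario A [scenario_config()].
#' @param design Design label.
#' @param estimates List of `"assoc_estimate"` objects (`NULL`s allowed).
#' @param avg_scale `"log"` (default) or `"response"`.
#' @return A one-row `data.frame` with the scenario parameters,
#'   `mean_log_estimate`, `mean_estimate`, `empirical_p`,
#'   `empirical_p_uncapped`, `n_used` and `n_degenerate`; all-`NA` summary
#'   columns when no replicate was usable.
#' @export
summarize_replicates <- function(scenario, design, estimates,
                                 avg_scale = c("log", "response")) {
  avg_scale <- match.arg(avg_scale)
  R <- length(estimates)
  usable <- vapply(estimates, function(e)
    !is.null(e) && isTRUE(e$converged) && is.finite(e$log_estimate),
    logical(1))
  logs <- vapply(estimates[usable], function(e) e$log_estimate, numeric(1))
  base <- data.frame(
    maf = scenario$maf, irr_disease = scenario$irr_disease,
    irr_death = scenario$irr_death,
    disease_mode = scenario$disease_baseline$mode,
    disease_shape = scenario$disease_baseline$shape,
    rarity_target = scenario$rarity_target,
    n_individuals = scenario$n_individuals,
    design = design, stringsAsFactors = FALSE)
  if (!length(logs)) {
    base$mean_log_estimate <- NA_real_
    base$mean_estimate <- NA_real_
    base$empirical_p <- NA_real_
    base$empirical_p_uncapped <- NA_real_
  } else {
    p <- empirical_p(logs)
    base$mean_log_estimate <- mean(logs)
    base$mean_estimate <- if (avg_scale == "log") exp(mean(logs))
                          else mean(exp(logs))
    base$empirical_p <- as.numeric(p)
    base$empirical_p_uncapped <- attr(p, "uncapped")
  }
  base$n_used <- sum(usable)
  base$n_degenerate <- R - sum(usable)
  base
}

## logistic fit of (intercept, slope) to expected genotype-group proportions;
## plain Newton on the expected-count score, no stochastic input
expected_logit_slope <- function(g, w_case, w_ctrl) {
  X <- cbind(1, g)
  n <- w_case + w_ctrl
  beta <- c(log(sum(w_case) / sum(w_ctrl)), 0)
  for (i in 1:50) {
    p <- stats::plogis(X %*% beta)
    score <- crossprod(X, w_case - n * p)
    info <- crossprod(X, X * as.vector(n * p * (1 - p)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta[2]
}

#' Large-sample log odds ratio implied by the classical design
#'
#' Deterministic oracle for the classical case-control estimate: computes
#' `P(disease by censor_age | g)` for g = 0, 1, 2 by quadrature
#' ([cumulative_incidence()]), forms the expected genotype distributions of
#' cases (diseased) and eligible controls (never diseased, including those
#' dead disease-free), and fits the one-covariate logistic model to these
#' expected proportions by Newton iteration. The returned slope is the
#' probability limit of the fitted per-allele log OR as the cohort grows.
#'
#' @param scenario A [scenario_config()].
#' @return The asymptotic per-allele log odds ratio.
#' @examples
#' analytic_or(scenario_config(maf = 0.25, irr_disease = 1,
#'                             irr_death = 1))  # exactly 0
#' @export
analytic_or <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  scenario <- resolve_scale(scenario)
  hz <- scenario_hazards(scenario)
  w <- hwe_probs(scenario$maf)
  cif <- vapply(0:2, function(g)
    cumulative_incidence(hz$dis, hz$death, g, scenario$censor_age),
    numeric(1))
  expected_logit_slope(0:2, w_case = w * cif, w_ctrl = w * (1 - cif))
}

#' Grid configuration for the full simulation study
#'
#' Defaults mirror the study grid: MAF \{0.1, 0.25, 0.5\}; disease IRR
#' \{0.5, 1.0, 1.1, 1.2, 1.5, 1.7, 2.0, 3.0\}; death IRR \{0.5, 0.75, 0.9,
#' 1.0, 1.1, 1.2, 1.5, 1.7, 2.0, 3.0\}; two disease baselines (mode 25 /
#' shape 0.95 and mode 50 / shape 0.1); rarity targets 0.22 (common) and
#' 0.025 (rare); cohorts of 10,000; 1000 replicates.
#'
#' @param maf,irr_disease,irr_death Numeric grids.
#' @param disease_baselines List of [gompertz_baseline()] objects.
#' @param death_baseline A single [gompertz_baseline()].
#' @param rarity_targets Numeric grid of lifetime-risk targets.
#' @param n_individuals Cohort size.
#' @param n_replicates Replicates per scenario.
#' @param base_seed Integer base seed.
#' @param designs Designs to run.
#' @param censor_age,controls_per_case Passed to [scenario_config()].
#' @return An object of class `"grid_config"`.
#' @export
grid_config <- function(maf = c(0.1, 0.25, 0.5),
                        irr_disease = c(0.5, 1.0, 1.1, 1.2, 1.5, 1.7, 2.0, 3.0),
                        irr_death = c(0.5, 0.75, 0.9, 1.0, 1.1, 1.2, 1.5,
                                      1.7, 2.0, 3.0),
                        disease_baselines = list(gompertz_baseline(25, 0.95),
                                                 gompertz_baseline(50, 0.1)),
                        death_baseline = gompertz_baseline(85, 4e-4),
                        rarity_targets = c(0.22, 0.025),
                        n_individuals = 10000, n_replicates = 1000,
                        base_seed = 1L,
                        designs = c("classical", "classical_age_adjusted",
                                    "incidence_density"),
                        censor_age = 90, controls_per_case = 5) {
  stopifnot(length(maf) >= 1, length(irr_disease) >= 1,
            length(irr_death) >= 1, length(disease_baselines) >= 1,
            length(rarity_targets) >= 1, n_replicates >= 1)
  if (inherits(disease_baselines, "gompertz_baseline"))
    disease_baselines <- list(disease_baselines)
  structure(list(maf = maf, irr_disease = irr_disease, irr_death = irr_death,
                 disease_baselines = disease_baselines,
                 death_baseline = death_baseline,
                 rarity_targets = rarity_targets,
                 n_individuals = n_individuals, n_replicates = n_replicates,
                 base_seed = base_seed, designs = designs,
                 censor_age = censor_age,
                 controls_per_case = controls_per_case),
            class = "grid_config")
}

#' Read a grid configuration from a YAML file
#'
#' The file holds the [grid_config()] fields as keys; baselines are maps
#' with `mode` and `shape` entries (`disease_baselines` is a list of such
#' maps). Missing keys fall back to the [grid_config()] defaults. Two
#' ready-made files ship with the package:
#' `system.file("config", "paper_defaults.yaml", package = "irrbias")` (the
#' full study grid) and `system.file("config", "smoke.yaml", package =
#' "irrbias")` (a minutes-scale smoke grid).
#'
#' @param path Path to a YAML file.
#' @return A `"grid_config"`.
#' @export
read_grid_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("disease_baselines", "death_baseline"))]
  if (!is.null(y$disease_baselines))
    args$disease_baselines <- lapply(y$disease_baselines, function(b)
      gompertz_baseline(b$mode, b$shape))
  if (!is.null(y$death_baseline))
    args$death_baseline <- gompertz_baseline(y$death_baseline$mode,
                                             y$death_baseline$shape)
  do.call(grid_config, args)
}

## expand a grid_config into a list of scenario_configs (row-major over
## expand.grid order, giving each cell a stable scenario index)
grid_scenarios <- function(grid) {
  cells <- expand.grid(maf = grid$maf, irr_disease = grid$irr_disease,
                       irr_death = grid$irr_death,
                       baseline = seq_along(grid$disease_baselines),
                       rarity = grid$rarity_targets,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    scenario_config(
      maf = cells$maf[i], irr_disease = cells$irr_disease[i],
      irr_death = cells$irr_death[i],
      disease_baseline = grid$disease_baselines[[cells$baseline[i]]],
      death_baseline = grid$death_baseline,
      rarity_target = cells$rarity[i],
      n_individuals = grid$n_individuals, censor_age = grid$censor_age,
      controls_per_case = grid$controls_per_case)
  })
}

#' Run the full simulation grid
#'
#' Sweeps the cross-product of the grid lists; for each scenario runs
#' [run_replicates()] and writes one [summarize_replicates()] row per design
#' to `output` (tab-separated), flushing after every scenario so partial
#' output stays valid. Rows also carry the deterministic [analytic_or()]
#' value and the true log IRR of disease. When `resume = TRUE` (default)
#' scenarios whose rows are already present in `output` are skipped, keyed
#' by (scenario parameters, design).
#'
#' Disease-scale calibration depends only on (baseline, rarity target,
#' censor age, MAF), so calibrations are cached across grid cells.
#'
#' @param grid A [grid_config()].
#' @param output Path of the results TSV.
#' @param resume Skip scenarios already present in `output`.
#' @param verbose Print per-scenario progress to `stderr`.
#' @return The full results `data.frame`, invisibly.
#' @export
run_grid <- function(grid, output, resume = TRUE, verbose = TRUE) {
  stopifnot(inherits(grid, "grid_config"))
  scenarios <- grid_scenarios(grid)
  done <- NULL
  if (resume && file.exists(output)) {
    done <- utils::read.delim(output, stringsAsFactors = FALSE)
  }
  key <- function(df) paste(df$maf, df$irr_disease, df$irr_death,
                            df$disease_mode, df$disease_shape,
                            df$rarity_target, df$design)
  done_keys <- if (is.null(done)) character(0) else key(done)
  scale_cache <- new.env(parent = emptyenv())
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    ck <- paste(sc$disease_baseline$mode, sc$disease_baseline$shape,
                sc$rarity_target, sc$censor_age, sc$maf)
    if (is.null(scale_cache[[ck]]))
      scale_cache[[ck]] <- resolve_scale(sc)$disease_scale
    sc$disease_scale <- scale_cache[[ck]]
    probe <- summarize_replicates(sc, grid$designs[1], list(NULL))
    if (all(key(probe) %in% done_keys)) next
    if (verbose)
      message(sprintf("[%d/%d] maf=%g irr_dis=%g irr_death=%g mode=%g target=%g",
                      i, length(scenarios), sc$maf, sc$irr_disease,
                      sc$irr_death, sc$disease_baseline$mode,
                      sc$rarity_target))
    reps <- run_replicates(sc, R = grid$n_replicates,
                           base_seed = grid$base_seed,
                           designs = grid$designs, scenario_index = i)
    a_or <- analytic_or(sc)
    rows <- do.call(rbind, lapply(grid$designs, function(d)
      summarize_replicates(sc, d, reps[[d]])))
    rows$analytic_log_or <- a_or
    rows$true_log_irr <- log(sc$irr_disease)
    new_keys <- key(rows)
    rows <- rows[!(new_keys %in% done_keys), , drop = FALSE]
    utils::write.table(rows, output, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(output),
                       append = file.exists(output))
    done_keys <- c(done_keys, new_keys)
  }
  invisible(utils::read.delim(output, stringsAsFactors = FALSE))
}

#' Quick diagnostic plots of grid results
#'
#' With `what = "estimates"`, plots the replicate-mean estimate against the
#' true disease IRR per design (the identity line marks no bias); with
#' `what = "pvalues"`, plots classical against incidence-density empirical
#' p-values on the -log10 scale (points below the diagonal are
#' classical-design excesses). Minimal base graphics, intended for
#' inspection rather than publication.
#'
#' @param results Results data frame from [run_grid()].
#' @param what `"estimates"` or `"pvalues"`.
#' @return `NULL`, invisibly.
#' @export
plot_grid_results <- function(results, what = c("estimates", "pvalues")) {
  what <- match.arg(what)
  if (what == "estimates") {
    designs <- unique(results$design)
    cols <- seq_along(designs)
    plot(exp(results$true_log_irr), results$mean_estimate,
         col = cols[match(results$design, designs)],
         xlab = "true IRR of disease", ylab = "replicate-mean estimate",
         log = "xy")
    graphics::abline(0, 1)
    graphics::legend("topleft", legend = designs, col = cols, pch = 1,
                     bty = "n")
  } else {
    wide <- merge(
      results[results$design == "classical",
              c("maf", "irr_disease", "irr_death", "disease_mode",
                "rarity_target", "empirical_p")],
      results[results$design == "incidence_density",
              c("maf", "irr_disease", "irr_death", "disease_mode",
                "rarity_target", "empirical_p")],
      by = c("maf", "irr_disease", "irr_death", "disease_mode",
             "rarity_target"), suffixes = c("_classical", "_matched"))
    eps <- 1e-4
    plot(-log10(wide$empirical_p_matched + eps),
         -log10(wide$empirical_p_classical + eps),
         xlab = "-log10 p (incidence density)",
         ylab = "-log10 p (classical)")
    graphics::abline(0, 1)
  }
  invisible(NULL)
}
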