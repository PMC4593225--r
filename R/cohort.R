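#' Scenario configuration for one cell of the simulation grid
#'
#' Bundles everything needed to simulate one longitudinal cohort: the
#' genotype distribution, the per-allele incidence rate ratios on the two
#' cause-specific hazards, the Gompertz baselines, the rarity of the disease
#' (either a target lifetime risk to calibrate to, or a pre-computed scaling
#' constant), the cohort size and the censoring age.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param irr_disease Per-allele incidence rate ratio for disease (> 0).
#' @param irr_death Per-allele incidence rate ratio for death (> 0).
#' @param disease_baseline [gompertz_baseline()] for disease; default mode
#'   50, shape 0.1 (the late-onset disease baseline).
#' @param death_baseline [gompertz_baseline()] for death; default mode 85,
#'   shape 0.0004.
#' @param rarity_target Target lifetime risk of disease by `censor_age`
#'   (population average, null genotype effects); default 0.22, the common
#'   disease. Ignored when `disease_scale` is supplied.
#' @param disease_scale Optional pre-computed disease-hazard scaling
#'   constant; `NULL` (default) means calibrate to `rarity_target`.
#' @param n_individuals Cohort size (default 10000).
#' @param censor_age Censoring age in years (default 90).
#' @param controls_per_case Matching/sampling ratio m (default 5).
#' @return An object of class `"scenario_config"`.
#' @examples
#' sc <- scenario_config(maf = 0.25, irr_disease = 1.5, irr_death = 0.5)
#' @export
scenario_config <- function(maf, irr_disease = 1, irr_death = 1,
                            disease_baseline = gompertz_baseline(50, 0.1),
                            death_baseline = gompertz_baseline(85, 4e-4),
                            rarity_target = 0.22, disease_scale = NULL,
                            n_individuals = 10000, censor_age = 90,
                            controls_per_case = 5) {
  hwe_probs(maf)  # validates maf
  stopifnot(irr_disease > 0, irr_death > 0,
            n_individuals >= 1, censor_age > 0, controls_per_case >= 1)
  if (!inherits(disease_baseline, "gompertz_baseline") ||
      !inherits(death_baseline, "gompertz_baseline"))
    stop("baselines must be gompertz_baseline objects")
  if (!is.null(disease_scale))
    stopifnot(is.numeric(disease_scale), length(disease_scale) == 1L,
              disease_scale >= 0, disease_scale <= 1)
  structure(list(maf = maf, irr_disease = irr_disease, irr_death = irr_death,
                 disease_baseline = disease_baseline,
                 death_baseline = death_baseline,
                 rarity_target = rarity_target, disease_scale = disease_scale,
                 n_individuals = as.integer(n_individuals),
                 censor_age = censor_age,
                 controls_per_case = as.integer(controls_per_case)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  sc <- if (is.null(x$disease_scale)) {
    sprintf("calibrated to lifetime risk %g", x$rarity_target)
  } else sprintf("scale %g", x$disease_scale)
  cat(sprintf(
    paste0("Scenario: n=%d, MAF %g, IRR(disease) %g, IRR(death) %g\n",
           "  disease baseline mode %g shape %g (%s)\n",
           "  death baseline mode %g shape %g; censored at %g years; 1:%d sampling\n"),
    x$n_individuals, x$maf, x$irr_disease, x$irr_death,
    x$disease_baseline$mode, x$disease_baseline$shape, sc,
    x$death_baseline$mode, x$death_baseline$shape,
    x$censor_age, x$controls_per_case))
  invisible(x)
}

#' Resolve the disease-hazard scaling constant of a scenario
#'
#' Returns the scenario with `disease_scale` filled in, calibrating to
#' `rarity_target` via [calibrate_scale()] when it is not supplied.
#' Calibration is deterministic, so resolving once before a replicate loop
#' avoids repeating the root-find.
#'
#' @param config A [scenario_config()].
#' @return The same scenario with a numeric `disease_scale`.
#' @export
resolve_scale <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$disease_scale)) {
    config$disease_scale <- calibrate_scale(
      config$disease_baseline,
      cs_hazard(config$death_baseline, scale = 1, log_irr = 0),
      maf = config$maf, target = config$rarity_target,
      censor_age = config$censor_age)
  }
  config
}

## cause-specific hazards implied by a resolved scenario
scenario_hazards <- function(config) {
  list(dis = cs_hazard(config$disease_baseline, scale = config$disease_scale,
                       log_irr = log(config$irr_disease)),
       death = cs_hazard(config$death_baseline, scale = 1,
                         log_irr = log(config$irr_death)))
}

#' Draw Hardy-Weinberg genotypes
#'
#' I.i.d. minor-allele counts with probabilities \eqn{(1-p)^2, 2p(1-p), p^2}.
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n Number of individuals.
#' @return Integer vector of minor-allele counts in \{0, 1, 2\}.
#' @export
draw_genotypes <- function(maf, n) {
  stopifnot(n >= 1)
  sample.int(3L, size = n, replace = TRUE, prob = hwe_probs(maf)) - 1L
}

#' Simulate a competing-risks cohort
#'
#' Generates a longitudinal cohort by cause-specific-hazard inversion: for
#' each individual with genotype g, a waiting time T solves
#' \eqn{H_{dis}(T,g) + H_{death}(T,g) = -\log U} with U uniform; individuals
#' with T at or beyond `censor_age` are censored there, and otherwise the
#' event is disease with probability
#' \eqn{h_{dis}(T,g) / [h_{dis}(T,g) + h_{death}(T,g)]}, else death.
#'
#' The RNG stream order is fixed and documented: (1) genotypes, (2) one
#' uniform waiting-time draw per individual, (3) one uniform cause-assignment
#' draw per individual (consumed for every individual, censored or not, so
#' the stream alignment does not depend on event outcomes).
#'
#' @param config A [scenario_config()]; the disease scale is resolved via
#'   [resolve_scale()] if needed.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   `(config, seed)`.
#' @return A `data.frame` of class `"cohort"` with columns `id`, `genotype`,
#'   `time` (age in years of first event or censoring) and `event` (factor
#'   with levels `disease`, `death`, `censored`), plus a `censor_age`
#'   attribute.
#' @examples
#' coh <- simulate_cohort(scenario_config(maf = 0.25, n_individuals = 500), seed = 1)
#' table(coh$event)
#' @export
simulate_cohort <- function(config, seed) {
  config <- resolve_scale(config)
  n <- config$n_individuals
  set.seed(seed)
  g <- draw_genotypes(config$maf, n)
  e <- -log(runif(n))
  u_cause <- runif(n)

  hz <- scenario_hazards(config)
  time <- numeric(n)
  event <- character(n)
  for (gg in 0:2) {
    idx <- which(g == gg)
    if (!length(idx)) next
    cap <- total_cumhaz(hz$dis, hz$death, gg, config$censor_age)
    cens <- e[idx] >= cap
    time[idx[cens]] <- config$censor_age
    event[idx[cens]] <- "censored"
    live <- idx[!cens]
    if (length(live)) {
      tt <- newton_invert(function(t) total_cumhaz(hz$dis, hz$death, gg, t),
                          function(t) total_hazard(hz$dis, hz$death, gg, t),
                          e[live], config$censor_age)
      p_dis <- hazard(hz$dis, gg, tt) /
        (hazard(hz$dis, gg, tt) + hazard(hz$death, gg, tt))
      time[live] <- tt
      event[live] <- ifelse(u_cause[live] < p_dis, "disease", "death")
    }
  }
  out <- data.frame(id = seq_len(n), genotype = g, time = time,
                    event = factor(event,
                                   levels = c("disease", "death", "censored")))
  attr(out, "censor_age") <- config$censor_age
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write / read a cohort as a tab-separated table
#'
#' Round-trip safe export with header columns `id`, `genotype`, `time`,
#' `event`; the censoring age is recovered on read as the maximum time of a
#' censored record (or the maximum time if none are censored).
#'
#' @param cohort A `"cohort"` data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `"cohort"` data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  df$time <- format(df$time, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "genotype", "time", "event") %in% names(df)))
  df$event <- factor(df$event, levels = c("disease", "death", "censored"))
  cens <- df$time[df$event == "censored"]
  attr(df, "censor_age") <- if (length(cens)) max(cens) else max(df$time)
  class(df) <- c("cohort", "data.frame")
  df
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$event)
  cat(sprintf("Competing-risks cohort: %d individuals (censored at %g years)\n",
              nrow(x), attr(x, "censor_age")))
  cat(sprintf("  disease %d, death %d, censored %d\n",
              tab[["disease"]], tab[["death"]], tab[["censored"]]))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}
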