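# Shared fixtures and independent oracles for the test suite.

# build a cohort object by hand (for sampling/estimator tests)
make_cohort <- function(genotype, time, event, censor_age = 90) {
  out <- data.frame(id = seq_along(genotype), genotype = as.integer(genotype),
                    time = time,
                    event = factor(event,
                                   levels = c("disease", "death", "censored")))
  attr(out, "censor_age") <- censor_age
  class(out) <- c("cohort", "data.frame")
  out
}

# exact conditional logistic log-likelihood, written independently of the
# fitting code: one case per set, likelihood exp(b*g_case)/sum_j exp(b*g_j)
cond_loglik <- function(beta, data) {
  sum(vapply(split(data, data$set_id), function(s) {
    beta * s$genotype[s$is_case == 1L] - log(sum(exp(beta * s$genotype)))
  }, numeric(1)))
}

# pull usable log estimates out of a run_replicates() design list
usable_logs <- function(lst) {
  ok <- vapply(lst, function(e)
    !is.null(e) && isTRUE(e$converged) && is.finite(e$log_estimate),
    logical(1))
  vapply(lst[ok], function(e) e$log_estimate, numeric(1))
}

# memoised heavy simulations shared between acceptance checks
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- expr
  .sim_cache[[key]]
}

common_scenario <- function(irr_disease = 1, irr_death = 1, maf = 0.25,
                            n = 10000, rarity = 0.22)
  scenario_config(maf = maf, irr_disease = irr_disease,
                  irr_death = irr_death, rarity_target = rarity,
                  n_individuals = n)

# classical-design replicate runs used by several acceptance properties
classical_runs <- function(irr_disease, irr_death, rarity, R = 200) {
  key <- paste("cls", irr_disease, irr_death, rarity, R)
  cached(key, {
    sc <- common_scenario(irr_disease, irr_death, rarity = rarity)
    usable_logs(run_replicates(sc, R = R, base_seed = 1,
                               designs = "classical")$classical)
  })
}
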