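#' Association estimate container
#'
#' @param log_estimate Estimated log odds ratio or log incidence rate ratio
#'   per minor allele.
#' @param std_err Asymptotic standard error from observed information.
#' @param design One of `"classical"`, `"classical_age_adjusted"`,
#'   `"incidence_density"`.
#' @param converged Logical convergence / non-separation flag.
#' @param n_cases,n_controls Counts.
#' @param loglik Optional numeric vector `c(null, final)` of log-likelihoods.
#' @return An object of class `"assoc_estimate"`.
#' @keywords internal
assoc_estimate <- function(log_estimate, std_err, design, converged,
                           n_cases, n_controls, loglik = NULL) {
  structure(list(log_estimate = log_estimate, std_err = std_err,
                 design = design, converged = converged,
                 n_cases = n_cases, n_controls = n_controls,
                 loglik = loglik),
            class = "assoc_estimate")
}

#' @export
print.assoc_estimate <- function(x, ...) {
  lab <- switch(x$design,
                incidence_density = "IRR (conditional logistic)",
                "OR (logistic)")
  cat(sprintf("%s design: %s = %.4f (log %.4f, SE %.4f)%s\n",
              x$design, lab, exp(x$log_estimate), x$log_estimate, x$std_err,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  %d cases, %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Logistic regression on a classical case-control sample
#'
#' Maximum-likelihood fit of
#' \eqn{\mathrm{logit}\, P(\mathrm{case}) = \beta_0 + \beta_1 g}
#' (optionally \eqn{+ \beta_2 \cdot \mathrm{age}}) with the minor-allele
#' count entering log-additively. `exp(log_estimate)` is the per-allele
#' odds ratio. Complete or quasi-complete separation and IRLS
#' non-convergence are flagged via `converged = FALSE`.
#'
#' @param data A `"case_control"` data frame from [sample_classical()].
#' @param adjust_age If `TRUE`, include a linear age term.
#' @return An `"assoc_estimate"`.
#' @examples
#' d <- data.frame(genotype = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)),
#'                 is_case = rep(c(1, 0), c(100, 100)),
#'                 age = runif(200, 0, 90))
#' class(d) <- c("case_control", "data.frame")
#' fit_logistic(d)  # log OR = log(27/7)
#' @export
fit_logistic <- function(data, adjust_age = FALSE) {
  n_cases <- sum(data$is_case == 1L)
  n_controls <- sum(data$is_case == 0L)
  if (n_cases < 1L || n_controls < 1L)
    stop("need at least one case and one control")
  if (length(unique(data$genotype)) < 2L)
    stop("genotype is constant; association not estimable")
  fml <- if (adjust_age) is_case ~ genotype + age else is_case ~ genotype
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[["genotype"]]
  se <- sqrt(diag(stats::vcov(fit)))[["genotype"]]
  # |log OR| beyond ~15 per allele or an exploded SE marks quasi-complete
  # separation that IRLS happened to "converge" through
  assoc_estimate(
    log_estimate = beta, std_err = se,
    design = if (adjust_age) "classical_age_adjusted" else "classical",
    converged = fit$converged && !sep && is.finite(se) &&
      abs(beta) < 15 && se < 50,
    n_cases = n_cases, n_controls = n_controls,
    loglik = c(null = -fit$null.deviance / 2, final = -fit$deviance / 2))
}

#' Conditional logistic regression on a time-matched sample
#'
#' Maximizes the conditional likelihood
#' \deqn{\prod_{\mathrm{sets}} \frac{e^{\beta g_{\mathrm{case}}}}
#'   {\sum_{j \in \mathrm{set}} e^{\beta g_j}}}
#' via [survival::clogit()]. With one case per matched set all tie-handling
#' methods coincide, so the Breslow form is used. `exp(log_estimate)`
#' estimates the per-allele incidence rate ratio. Sets in which every member
#' shares one genotype contribute a constant and are counted; a design in
#' which all sets are uninformative, or a monotone likelihood (separation),
#' is flagged via `converged = FALSE`.
#'
#' @param data A `"matched_design"` data frame from
#'   [sample_incidence_density()].
#' @return An `"assoc_estimate"` whose `loglik` field holds the null
#'   (beta = 0) and maximized conditional log-likelihoods; the null value is
#'   \eqn{-\sum_{\mathrm{sets}} \log(\mathrm{set\ size})}.
#' @export
fit_conditional_logistic <- function(data) {
  if (!nrow(data)) stop("empty matched design")
  n_sets <- length(unique(data$set_id))
  inform <- tapply(data$genotype, data$set_id,
                   function(g) length(unique(g)) > 1L)
  n_inform <- sum(inform)
  n_cases <- sum(data$is_case == 1L)
  n_controls <- sum(data$is_case == 0L)
  if (n_inform == 0L)
    return(assoc_estimate(NA_real_, NA_real_, "incidence_density", FALSE,
                          n_cases, n_controls))
  sep <- FALSE
  df <- as.data.frame(data)
  df$.stop <- 1
  # conditional logistic likelihood == stratified Cox partial likelihood at a
  # single time point; one case per set, so every ties method coincides
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.stop, is_case) ~ genotype +
                      survival::strata(set_id),
                    data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 100L)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[["genotype"]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  est <- assoc_estimate(
    log_estimate = beta, std_err = se, design = "incidence_density",
    converged = !sep && is.finite(beta) && is.finite(se) && abs(beta) < 20,
    n_cases = n_cases, n_controls = n_controls,
    loglik = c(null = fit$loglik[1], final = fit$loglik[2]))
  est$n_informative_sets <- n_inform
  est$n_sets <- n_sets
  est
}
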