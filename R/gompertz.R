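#' Gompertz baseline hazard parameterized by density mode and shape
#'
#' Constructs a Gompertz baseline hazard
#' \deqn{h_0(t) = b \, e^{b (t - M)},}
#' where `M` (`mode`) is the age in years at which the Gompertz density peaks
#' and `b` (`shape`) is the rate parameter in 1/years. In this
#' parameterization the hazard evaluated at the mode equals the shape, and
#' the standard Gompertz level parameter is \eqn{\lambda = b e^{-bM}}.
#'
#' @param mode Age in years of the density mode; must be positive.
#' @param shape Rate parameter in 1/years; must be positive.
#' @return An object of class `"gompertz_baseline"`.
#' @examples
#' death <- gompertz_baseline(mode = 85, shape = 4e-4)
#' disease <- gompertz_baseline(mode = 50, shape = 0.1)
#' @export
gompertz_baseline <- function(mode, shape) {
  stopifnot(is.numeric(mode), length(mode) == 1L, is.finite(mode),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (mode <= 0) stop("'mode' must be > 0")
  if (shape <= 0) stop("'shape' must be > 0")
  structure(list(mode = mode, shape = shape), class = "gompertz_baseline")
}

#' @export
print.gompertz_baseline <- function(x, ...) {
  cat(sprintf("Gompertz baseline: mode %g years, shape %g /year\n",
              x$mode, x$shape))
  invisible(x)
}

#' Cause-specific hazard with a per-allele multiplicative genotype effect
#'
#' Combines a Gompertz baseline with a dimensionless scaling constant and a
#' log-linear per-minor-allele effect:
#' \deqn{h(t, g) = c \, h_0(t) \, e^{g \beta},}
#' where `c` = `scale`, \eqn{\beta} = `log_irr`, and `g` is the minor-allele
#' count (0, 1 or 2). The scaling constant controls the lifetime risk of the
#' event (fixed at 1 for death); the incidence rate ratio per allele is
#' `exp(log_irr)`.
#'
#' @param baseline A [gompertz_baseline()] object.
#' @param scale Dimensionless multiplicative constant in \[0, 1\].
#' @param log_irr Per-minor-allele log incidence-rate ratio.
#' @return An object of class `"cs_hazard"`.
#' @examples
#' dis <- cs_hazard(gompertz_baseline(50, 0.1), scale = 0.005, log_irr = log(1.5))
#' hazard(dis, g = 2, t = 60)
#' @export
cs_hazard <- function(baseline, scale = 1, log_irr = 0) {
  if (!inherits(baseline, "gompertz_baseline"))
    stop("'baseline' must be a gompertz_baseline object")
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(log_irr), length(log_irr) == 1L, is.finite(log_irr))
  if (scale < 0 || scale > 1) stop("'scale' must lie in [0, 1]")
  structure(list(baseline = baseline, scale = scale, log_irr = log_irr),
            class = "cs_hazard")
}

#' @export
print.cs_hazard <- function(x, ...) {
  cat(sprintf(
    "Cause-specific hazard: mode %g, shape %g, scale %g, IRR/allele %g\n",
    x$baseline$mode, x$baseline$shape, x$scale, exp(x$log_irr)))
  invisible(x)
}

check_genotype <- function(g) {
  if (!all(g %in% c(0, 1, 2))) stop("genotype must be 0, 1 or 2 minor alleles")
  g
}

check_age <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("age 't' must be finite and >= 0")
  t
}

#' Evaluate a cause-specific hazard rate
#'
#' @param h A [cs_hazard()] object.
#' @param g Minor-allele count in \{0, 1, 2\} (scalar).
#' @param t Age(s) in years, non-negative; vectorized.
#' @return Hazard rate(s) per year.
#' @export
hazard <- function(h, g, t) {
  check_genotype(g)
  check_age(t)
  b <- h$baseline$shape
  h$scale * exp(g * h$log_irr) * b * exp(b * (t - h$baseline$mode))
}

#' Closed-form cumulative cause-specific hazard
#'
#' Integral of [hazard()] from 0 to `t`:
#' \eqn{H(t, g) = c \, e^{g\beta} e^{-bM} (e^{bt} - 1)}.
#'
#' @inheritParams hazard
#' @return Dimensionless cumulative hazard(s); 0 at `t = 0`.
#' @export
cumulative_hazard <- function(h, g, t) {
  check_genotype(g)
  check_age(t)
  b <- h$baseline$shape
  h$scale * exp(g * h$log_irr) * exp(-b * h$baseline$mode) * expm1(b * t)
}

## total (all-cause) cumulative hazard and its derivative, vectorized in t
total_cumhaz <- function(dis, death, g, t) {
  cumulative_hazard(dis, g, t) + cumulative_hazard(death, g, t)
}

total_hazard <- function(dis, death, g, t) {
  hazard(dis, g, t) + hazard(death, g, t)
}

#' Invert the total cumulative hazard of two competing events
#'
#' Solves \eqn{H_{dis}(T, g) + H_{death}(T, g) = e} for `T`. This is the
#' inversion step of the competing-risks simulation algorithm: an
#' individual's waiting time to the first event is the total cumulative
#' hazard evaluated at an Exp(1) draw.
#'
#' The total cumulative hazard is strictly increasing and convex (a sum of
#' two scaled exponentials), so a damped Newton iteration started from an
#' upper bracket converges monotonically from above. Solutions satisfy the
#' equation to absolute tolerance 1e-10 on the cumulative-hazard scale.
#'
#' @param dis,death [cs_hazard()] objects; at least one must have positive
#'   scale.
#' @param g Minor-allele count in \{0, 1, 2\}.
#' @param e Target cumulative hazard(s), non-negative; vectorized.
#' @return Age(s) `T` in years with total cumulative hazard equal to `e`.
#' @export
invert_total_cumulative_hazard <- function(dis, death, g, e) {
  check_genotype(g)
  if (any(!is.finite(e)) || any(e < 0)) stop("'e' must be finite and >= 0")
  if (dis$scale <= 0 && death$scale <= 0)
    stop("total cumulative hazard is identically zero: target unattainable")
  if (!length(e)) return(numeric(0))
  A <- function(t) total_cumhaz(dis, death, g, t)
  out <- numeric(length(e))
  pos <- e > 0
  if (any(pos)) {
    emax <- max(e[pos])
    upper <- 1
    while (is.finite(A(upper)) && A(upper) < emax) {
      upper <- upper * 2
      if (upper > 1e9) stop("target cumulative hazard unattainable")
    }
    if (!is.finite(A(upper))) {
      # shrink back into the finite range while keeping A(upper) >= emax
      lo <- upper / 2
      hi <- upper
      repeat {
        mid <- (lo + hi) / 2
        if (!is.finite(A(mid))) hi <- mid
        else if (A(mid) >= emax) { upper <- mid; break }
        else lo <- mid
      }
    }
    out[pos] <- newton_invert(A, function(t) total_hazard(dis, death, g, t),
                              e[pos], upper)
  }
  out
}

## vectorized safeguarded Newton for increasing convex A(); start from an
## upper bracket so iterates decrease monotonically to the root
newton_invert <- function(A, a, e, upper, tol = 1e-12, maxit = 200L) {
  t <- rep(upper, length(e))
  for (i in seq_len(maxit)) {
    f <- A(t) - e
    if (all(abs(f) <= tol)) break
    step <- f / pmax(a(t), .Machine$double.xmin)
    # stop once steps are at the floating-point resolution of t itself
    if (all(abs(step) <= 1e-14 * pmax(t, 1))) break
    t <- pmax(t - step, 0)
  }
  t
}

#' Cumulative incidence function under competing risks
#'
#' Probability of experiencing the `dis` event by age `t` in the presence of
#' the competing `death` event, for an individual with genotype `g`:
#' \deqn{\mathrm{CIF}(t, g) = \int_0^t h_{dis}(s, g)\,
#'   e^{-[H_{dis}(s,g) + H_{death}(s,g)]}\, ds,}
#' evaluated by adaptive quadrature (relative tolerance 1e-8).
#'
#' @inheritParams invert_total_cumulative_hazard
#' @param t Age in years (scalar).
#' @return A probability in \[0, 1\].
#' @export
cumulative_incidence <- function(dis, death, g, t) {
  check_genotype(g)
  check_age(t)
  stopifnot(length(t) == 1L)
  if (t == 0 || dis$scale == 0) return(0)
  f <- function(s) {
    v <- hazard(dis, g, s) * exp(-total_cumhaz(dis, death, g, s))
    v[!is.finite(v)] <- 0
    v
  }
  val <- stats::integrate(f, 0, t, rel.tol = 1e-8, abs.tol = 1e-12,
                          subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf Minor allele frequency in (0, 0.5\].
#' @return Probabilities of 0, 1 and 2 minor alleles:
#'   \eqn{(1-p)^2, 2p(1-p), p^2}.
#' @export
hwe_probs <- function(maf) {
  stopifnot(is.numeric(maf), length(maf) == 1L, is.finite(maf))
  if (maf <= 0 || maf > 0.5) stop("'maf' must lie in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Calibrate the disease-hazard scaling constant to a target lifetime risk
#'
#' Finds the constant `c` such that the population-average cumulative
#' incidence of disease at `censor_age`,
#' \eqn{\sum_g \mathrm{HWE}(g)\,\mathrm{CIF}(c, g, \mathrm{censor\_age})},
#' equals `target`, with genotype effects held at their null values (log IRR
#' of 0 for both events) during calibration. The root is bracketed on the
#' log scale, where the marginal CIF is strictly increasing in `c`.
#'
#' @param dis_baseline [gompertz_baseline()] for disease.
#' @param death [cs_hazard()] for the competing event.
#' @param maf Minor allele frequency in (0, 0.5\].
#' @param target Target lifetime-risk probability, strictly between 0 and
#'   the marginal CIF at `c = 1`.
#' @param censor_age End of follow-up in years (default 90).
#' @return The scaling constant `c`; plugging it back reproduces `target`
#'   to absolute tolerance 1e-6.
#' @examples
#' death <- cs_hazard(gompertz_baseline(85, 4e-4))
#' calibrate_scale(gompertz_baseline(50, 0.1), death, maf = 0.25,
#'                 target = 0.22)
#' @export
calibrate_scale <- function(dis_baseline, death, maf, target,
                            censor_age = 90) {
  stopifnot(is.numeric(target), length(target) == 1L)
  if (target <= 0) stop("'target' must be > 0")
  w <- hwe_probs(maf)
  death0 <- cs_hazard(death$baseline, scale = death$scale, log_irr = 0)
  marginal <- function(cc) {
    dis <- cs_hazard(dis_baseline, scale = cc, log_irr = 0)
    sum(w * vapply(0:2, function(g)
      cumulative_incidence(dis, death0, g, censor_age), numeric(1)))
  }
  cif1 <- marginal(1)
  if (target >= cif1)
    stop(sprintf(
      "target lifetime risk %.4g unattainable: marginal CIF at scale 1 is %.4g",
      target, cif1))
  lo <- -1e-3
  while (marginal(exp(lo)) > target) {
    lo <- lo * 4
    if (lo < -400) stop("calibration bracket failed")
  }
  r <- stats::uniroot(function(lc) marginal(exp(lc)) - target,
                      lower = lo, upper = 0, tol = 1e-13)
  exp(r$root)
}
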