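#' Classical (unrelated) case-control sample from a cohort
#'
#' Cases are all individuals diseased before the censoring age. Eligible
#' controls are all individuals never diseased during follow-up; by default
#' this includes individuals who died disease-free (set `survivors_only =
#' TRUE` to restrict controls to individuals alive and disease-free at the
#' end of follow-up). When more than `ratio` times as many eligible controls
#' exist as cases, controls are subsampled uniformly at random without
#' replacement at a 1:`ratio` ratio; otherwise all are kept.
#'
#' Each case carries its onset age; each control is assigned an age drawn
#' uniformly on (0, `censor_age`), mimicking an age covariate collected at an
#' arbitrary time during the sampling period.
#'
#' @param cohort A `"cohort"` data frame from [simulate_cohort()] or
#'   [read_cohort()].
#' @param ratio Controls per case (default 5).
#' @param censor_age End of follow-up in years; defaults to the cohort's
#'   `censor_age` attribute.
#' @param survivors_only If `TRUE`, only censored (alive, disease-free)
#'   individuals are eligible controls.
#' @return A `data.frame` of class `"case_control"` with columns `genotype`,
#'   `is_case` (0/1) and `age`, and attributes `n_cases`, `n_controls` and
#'   `degenerate` (`TRUE` when the cohort has no disease cases, in which
#'   case the data frame has zero rows).
#' @export
sample_classical <- function(cohort, ratio = 5,
                             censor_age = attr(cohort, "censor_age"),
                             survivors_only = FALSE) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) >= 1, ratio >= 1)
  if (is.null(censor_age)) censor_age <- max(cohort$time)
  case_idx <- which(cohort$event == "disease" & cohort$time < censor_age)
  elig <- if (survivors_only) which(cohort$event == "censored")
          else which(cohort$event != "disease")
  if (!length(case_idx)) {
    out <- data.frame(genotype = integer(0), is_case = integer(0),
                      age = numeric(0))
    attr(out, "n_cases") <- 0L
    attr(out, "n_controls") <- 0L
    attr(out, "degenerate") <- TRUE
    class(out) <- c("case_control", "data.frame")
    return(out)
  }
  n_ctrl_target <- ratio * length(case_idx)
  ctrl_idx <- if (length(elig) > n_ctrl_target) {
    elig[sample.int(length(elig), n_ctrl_target)]
  } else elig
  out <- data.frame(
    genotype = c(cohort$genotype[case_idx], cohort$genotype[ctrl_idx]),
    is_case = rep(c(1L, 0L), c(length(case_idx), length(ctrl_idx))),
    age = c(cohort$time[case_idx], runif(length(ctrl_idx), 0, censor_age)))
  attr(out, "n_cases") <- length(case_idx)
  attr(out, "n_controls") <- length(ctrl_idx)
  attr(out, "degenerate") <- FALSE
  class(out) <- c("case_control", "data.frame")
  out
}

#' Incidence density (time-matched) sample from a cohort
#'
#' For each disease case with onset age t, the risk set is every other
#' individual still under observation and event-free just after t, i.e.
#' those with recorded time strictly greater than t (the strict inequality
#' excludes the index case itself and resolves hypothetical ties
#' conservatively). `m` controls are drawn uniformly at random without
#' replacement from the risk set; when fewer than `m` are eligible the
#' smaller set is kept, and only cases with an empty risk set are dropped
#' (their count is reported). Individuals may serve as controls for several
#' cases and may later become cases themselves — excluding future cases
#' from risk sets would bias the rate-ratio estimate.
#'
#' @param cohort A `"cohort"` data frame.
#' @param m Controls per matched set (default 5).
#' @return A long `data.frame` of class `"matched_design"` with columns
#'   `set_id`, `is_case` (0/1), `genotype` and `match_age` (the case's onset
#'   age, shared by the whole set), plus attributes `n_sets`, `n_dropped`
#'   and `degenerate`.
#' @export
sample_incidence_density <- function(cohort, m = 5) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) >= 1, m >= 1)
  case_idx <- which(cohort$event == "disease")
  if (!length(case_idx)) {
    out <- data.frame(set_id = integer(0), is_case = integer(0),
                      genotype = integer(0), match_age = numeric(0))
    attr(out, "n_sets") <- 0L
    attr(out, "n_dropped") <- 0L
    attr(out, "degenerate") <- TRUE
    class(out) <- c("matched_design", "data.frame")
    return(out)
  }
  ord <- order(cohort$time)
  sorted_time <- cohort$time[ord]
  n <- nrow(cohort)

  ctrls <- vector("list", length(case_idx))
  for (k in seq_along(case_idx)) {
    t <- cohort$time[case_idx[k]]
    # positions in sorted order with time strictly greater than t
    first_after <- findInterval(t, sorted_time) + 1L
    if (first_after > n) next  # empty risk set: drop this case
    n_risk <- n - first_after + 1L
    take <- if (n_risk > m) {
      first_after - 1L + sample.int(n_risk, m)
    } else first_after:n
    ctrls[[k]] <- ord[take]
  }
  kept <- which(!vapply(ctrls, is.null, logical(1)))
  nc <- lengths(ctrls[kept])
  out <- if (!length(kept)) {
    data.frame(set_id = integer(0), is_case = integer(0),
               genotype = integer(0), match_age = numeric(0))
  } else data.frame(
    set_id = rep.int(seq_along(kept), nc + 1L),
    is_case = unlist(lapply(nc, function(k) rep(c(1L, 0L), c(1L, k)))),
    genotype = cohort$genotype[unlist(
      mapply(c, case_idx[kept], ctrls[kept], SIMPLIFY = FALSE))],
    match_age = rep.int(cohort$time[case_idx[kept]], nc + 1L))
  attr(out, "n_sets") <- length(kept)
  attr(out, "n_dropped") <- length(case_idx) - length(kept)
  attr(out, "degenerate") <- length(kept) == 0L
  class(out) <- c("matched_design", "data.frame")
  out
}

#' Export sampled designs as tab-separated tables
#'
#' Classical designs are written with columns `genotype`, `is_case`, `age`;
#' matched designs with `set_id`, `is_case`, `genotype`, `match_age`.
#'
#' @param design A `"case_control"` or `"matched_design"` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "case_control") ||
              inherits(design, "matched_design"))
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sampled design written by [write_design()]
#'
#' The design type is inferred from the header.
#'
#' @param path File path.
#' @return A `"case_control"` or `"matched_design"` data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("set_id" %in% names(df)) {
    attr(df, "n_sets") <- length(unique(df$set_id))
    attr(df, "n_dropped") <- NA_integer_
    attr(df, "degenerate") <- nrow(df) == 0L
    class(df) <- c("matched_design", "data.frame")
  } else {
    attr(df, "n_cases") <- sum(df$is_case == 1L)
    attr(df, "n_controls") <- sum(df$is_case == 0L)
    attr(df, "degenerate") <- !any(df$is_case == 1L)
    class(df) <- c("case_control", "data.frame")
  }
  df
}
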