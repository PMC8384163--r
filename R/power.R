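#' Required sample size from variance components
#'
#' Normal-approximation (z-based) sample-size formulas driven by the
#' variance decomposition of a reproducibility study.  The detectable
#' difference is `delta = percent_difference / 100 * grand_mean`.
#' \describe{
#'   \item{two_independent_groups}{cross-sectional comparison (e.g.
#'     patients vs controls), powered by the between-subject dispersion:
#'     per-group `n = ceil(2 * ((z_{1-alpha/2} + z_power) *
#'     inter_individual_sd / delta)^2)`; the reported headline is the total
#'     `2n`.}
#'   \item{within_subject}{longitudinal change in the same individual,
#'     powered by the technical (between-scan) dispersion:
#'     `n = ceil(((z_{1-alpha/2} + z_power) * inter_assay_sd / delta)^2)`,
#'     floored at 3.}
#' }
#' An optional iterative t-distribution refinement replaces the normal
#' quantiles with t quantiles at the implied degrees of freedom.
#'
#' @param components a [variance_components()] object.
#' @param design `"two_independent_groups"` or `"within_subject"`.
#' @param power target power in (0, 1) (default 0.80).
#' @param percent_difference detectable difference as a percent of the
#'   grand mean (default 10).
#' @param alpha two-sided significance level (default 0.05).
#' @param use_t apply the iterative t refinement (default `FALSE`).
#' @return list with `design`, `n` (headline count: total across both
#'   groups, or the within-subject count), `n_per_group` (two-group only),
#'   `delta`, `sd_used`, `degenerate` (`TRUE` when the relevant SD is 0 and
#'   the floor was returned).
#' @export
required_sample_size <- function(components,
                                 design = c("two_independent_groups",
                                            "within_subject"),
                                 power = 0.80, percent_difference = 10,
                                 alpha = 0.05, use_t = FALSE) {
  stopifnot(inherits(components, "variance_components"))
  design <- match.arg(design)
  if (power <= 0 || power >= 1) stop("`power` must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (percent_difference <= 0) stop("`percent_difference` must be positive")
  delta <- percent_difference / 100 * components$grand_mean
  sdv <- if (design == "two_independent_groups")
    components$inter_individual_sd else components$inter_assay_sd
  floor_n <- if (design == "two_independent_groups") 2L else 3L
  if (sdv == 0) {
    n <- floor_n
    return(list(design = design,
                n = if (design == "two_independent_groups") 2L * n else n,
                n_per_group = if (design == "two_independent_groups") n else NA,
                delta = delta, sd_used = sdv, degenerate = TRUE))
  }
  zq <- function(n_df) {
    if (use_t && is.finite(n_df))
      stats::qt(1 - alpha / 2, n_df) + stats::qt(power, n_df)
    else stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  }
  raw_n <- function(z) {
    if (design == "two_independent_groups") 2 * (z * sdv / delta)^2
    else (z * sdv / delta)^2
  }
  n <- ceiling(raw_n(zq(Inf)))
  if (use_t) {
    for (it in 1:25) {
      df <- if (design == "two_independent_groups") 2 * n - 2 else n - 1
      n2 <- ceiling(raw_n(zq(max(df, 2))))
      if (n2 == n) break
      n <- n2
    }
  }
  n <- max(n, floor_n)
  list(design = design,
       n = if (design == "two_independent_groups") 2L * n else as.integer(n),
       n_per_group = if (design == "two_independent_groups") as.integer(n)
                     else NA,
       delta = delta, sd_used = sdv, degenerate = FALSE)
}

#' Sample-size projection table
#'
#' Evaluates [required_sample_size()] for every measure in a reproducibility
#' table over a grid of designs, powers and detectable differences — the
#' trial-planning summary of a multisite study.  Measures whose variance
#' components cannot be computed are flagged rather than failing the table.
#'
#' @param table a [measure_table()].
#' @param powers powers to tabulate (default `c(0.80, 0.90)`).
#' @param differences percent differences (default `c(5, 10, 20)`).
#' @param alpha two-sided significance level (default 0.05).
#' @param use_t pass-through to [required_sample_size()].
#' @return data.frame with columns `measure`, `design`, `power`,
#'   `percent_difference`, `n` (headline count), `n_per_group`, `note`.
#' @export
power_table <- function(table, powers = c(0.80, 0.90),
                        differences = c(5, 10, 20), alpha = 0.05,
                        use_t = FALSE) {
  stopifnot(inherits(table, "measure_table"))
  measures <- unique(table$measure)
  designs <- c("two_independent_groups", "within_subject")
  out <- list()
  for (msr in measures) {
    vc <- tryCatch(variance_components(table, msr), error = function(e) e)
    for (des in designs) for (pw in powers) for (df in differences) {
      row <- data.frame(measure = msr, design = des, power = pw,
                        percent_difference = df, n = NA_integer_,
                        n_per_group = NA_integer_, note = "",
                        stringsAsFactors = FALSE)
      if (inherits(vc, "error")) {
        row$note <- "insufficient data"
      } else {
        r <- required_sample_size(vc, des, power = pw,
                                  percent_difference = df, alpha = alpha,
                                  use_t = use_t)
        row$n <- r$n
        row$n_per_group <- if (is.na(r$n_per_group)) NA_integer_
                           else r$n_per_group
        if (r$degenerate) row$note <- "zero variance: floor returned"
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
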