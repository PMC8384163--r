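#' Phantom accuracy workflow
#'
#' Runs the phantom arm of a multisite harmonization study end to end and
#' summarises accuracy and reproducibility across sites.  Two input modes:
#'
#' \describe{
#'   \item{table mode}{`phantom_table` is a data.frame of per-site phantom
#'     measurements (`site`, `measure`, `value`, `reference`), e.g.
#'     [table2_phantom()]; maps are not refitted.}
#'   \item{simulation mode}{`n_sites` digital copies of the calibrated vial
#'     phantom are generated with [make_vial_phantom_truth()], perturbed by
#'     per-site [site_effect()]s (signal gain, transmit-field scaling),
#'     acquired with [simulate_acquisition()], fitted with [fit_adc()] /
#'     [fit_t1_vfa()] / [compute_mtr()], and measured per vial region.  The
#'     organ-volume measure comes from a shared [make_pancreas_truth()]
#'     contour set.  The `"non_standardized"` variant fits ADC from the
#'     (0, 800) b-pair and T1 without B1 correction.}
#' }
#'
#' For every measurement with a calibrated reference the percent difference
#' is computed; measures without references are summarised by their
#' cross-site coefficient of variation.
#'
#' @param phantom_table optional table-mode input (see above).
#' @param n_sites number of simulated sites (simulation mode, default 5).
#' @param site_effects optional list of `n_sites` [site_effect()]s.
#' @param grid simulation grid for the mapping acquisitions (default
#'   [default_phantom_grid()]).
#' @param anatomical_grid grid of the anatomical series the organ phantom is
#'   traced on (default [default_phantom_grid()]); it may differ from the
#'   mapping grid, as anatomical scans are usually higher resolution.
#' @param noise_sigma Rician noise scale in signal units (default 0).
#' @param b1_amplitude transmit-field deviation of each simulated scanner
#'   (default 0.1).
#' @param variant `"standardized"` (default) or `"non_standardized"`.
#' @param seed master seed (simulation mode).
#' @param out_dir optional directory; when given, the report is written as
#'   `phantom_report.json` plus CSVs.
#' @return a report list with elements `mode`, `variant`, `measurements`,
#'   `percent_differences`, `accuracy` (per measure-family mean/max percent
#'   difference), and `cvs`.
#' @export
run_phantom_workflow <- function(phantom_table = NULL, n_sites = 5L,
                                 site_effects = NULL,
                                 grid = default_phantom_grid(),
                                 anatomical_grid = default_phantom_grid(),
                                 noise_sigma = 0, b1_amplitude = 0.1,
                                 variant = c("standardized",
                                             "non_standardized"),
                                 seed = 1L, out_dir = NULL) {
  variant <- match.arg(variant)
  if (is.null(phantom_table)) {
    phantom_table <- simulate_phantom_sites(n_sites, site_effects, grid,
                                            anatomical_grid, noise_sigma,
                                            b1_amplitude, variant, seed)
    mode <- "simulation"
  } else {
    stopifnot(is.data.frame(phantom_table),
              all(c("site", "measure", "value") %in% names(phantom_table)))
    if (is.null(phantom_table$reference))
      phantom_table$reference <- NA_real_
    mode <- "table"
  }
  pt <- phantom_table[!is.na(phantom_table$value), , drop = FALSE]

  has_ref <- !is.na(pt$reference)
  pd <- pt[has_ref, , drop = FALSE]
  pd$percent_difference <- percent_difference(pd$value, pd$reference)
  # family summaries: all T1 vials pooled, everything else per measure
  fam <- ifelse(grepl("^t1_vial", pd$measure), "t1", pd$measure)
  accuracy <- do.call(rbind, lapply(unique(fam), function(f) {
    x <- pd$percent_difference[fam == f]
    data.frame(measure = f, n = length(x),
               mean_percent_difference = mean(x),
               max_percent_difference = max(x), stringsAsFactors = FALSE)
  }))
  no_ref <- unique(pt$measure[!has_ref])
  cvs <- do.call(rbind, lapply(no_ref, function(msr) {
    v <- pt$value[pt$measure == msr]
    data.frame(measure = msr, n = length(v),
               cv_percent = if (length(v) >= 2) coefficient_of_variation(v)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  report <- list(workflow = "phantom", mode = mode, variant = variant,
                 measurements = pt, percent_differences = pd,
                 accuracy = accuracy, cvs = cvs)
  if (!is.null(out_dir)) write_report(report, out_dir, "phantom")
  report
}

# Simulate per-site phantom acquisitions, fit maps, and measure vials.
simulate_phantom_sites <- function(n_sites, site_effects, grid,
                                   anatomical_grid, noise_sigma,
                                   b1_amplitude, variant, seed) {
  if (!is.null(site_effects) && length(site_effects) != n_sites)
    stop("`site_effects` must have one entry per site")
  pancreas <- make_pancreas_truth(anatomical_grid, volume_ml = 89,
                                  seed = derive_seed(seed, 999L))
  rows <- list()
  for (j in seq_len(n_sites)) {
    eff <- if (is.null(site_effects)) site_effect() else site_effects[[j]]
    spec <- make_vial_phantom_truth(grid, noise_sigma = noise_sigma,
                                    b1_amplitude = b1_amplitude,
                                    seed = derive_seed(seed, j))
    spec$s0_map$data <- spec$s0_map$data * eff$gain_factor
    # b1_scale is a transmitter miscalibration: it perturbs the actual
    # transmit field but is NOT captured by the site's correction map
    correction_field <- spec$b1_field
    spec$b1_field$data <- spec$b1_field$data * eff$b1_scale
    vfa <- simulate_acquisition(spec, "vfa", seed = derive_seed(seed, 10L + j))
    dwi <- simulate_acquisition(spec, "dwi", seed = derive_seed(seed, 20L + j))
    mt <- simulate_acquisition(spec, "mt", seed = derive_seed(seed, 30L + j))
    t1_map <- if (variant == "standardized")
      fit_t1_vfa(vfa, b1 = b1_map(correction_field))
    else fit_t1_vfa(vfa, b1 = NULL)
    adc_map <- if (variant == "standardized") fit_adc(dwi, 200, 800)
               else fit_adc(dwi, 0, 800)
    mtr_map <- compute_mtr(mt)
    region_mean <- function(map, lab)
      mean(map$volume$data[spec$labels == lab], na.rm = TRUE)
    site <- sprintf("site%02d", j)
    for (v in seq_len(nrow(spec$vials))) {
      vv <- spec$vials[v, ]
      map <- switch(vv$parameter, t1_ms = t1_map, adc_mm2_s = adc_map,
                    mtr = mtr_map, fat_fraction = NULL)
      value <- if (is.null(map))
        mean(spec$truth$fat_fraction$volume$data[spec$labels == vv$label])
      else region_mean(map, vv$label)
      ref <- if (vv$parameter %in% c("t1_ms")) vv$truth else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, measure = vv$name, value = value, reference = ref,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, measure = "volume",
      value = pancreas_volume(pancreas$contours),
      reference = pancreas$volume_ml, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Volunteer reproducibility workflow
#'
#' Runs the travelling-volunteer arm: assembles the per-scan measure table
#' and applies the full reproducibility battery — mean across-site CV per
#' measure, Friedman test of a site effect, pairwise rank tests, the
#' inter-individual vs inter-assay variance decomposition, and the
#' sample-size projection table.  Input modes:
#'
#' \describe{
#'   \item{table mode}{`table` is a ready [measure_table()], e.g.
#'     [table2_volunteers()].}
#'   \item{scan mode}{`scans` is a list of per-scan inputs
#'     `list(subject, site, contours, maps, weight_kg, hepatic)`; measures
#'     are computed with [compute_scan_measures()].}
#'   \item{simulation mode}{`design` is a [study_design()]; the table comes
#'     from [simulate_multisite_study()].}
#' }
#'
#' Subjects observed at fewer than two sites are excluded from per-subject
#' statistics with a warning; statistics that remain impossible for a
#' measure are reported as `NA` with a note rather than aborting the run.
#'
#' @param table optional [measure_table()].
#' @param scans optional list of per-scan inputs (see above).
#' @param design optional [study_design()].
#' @param site_effects optional site effects for simulation mode.
#' @param powers,differences,alpha passed to [power_table()].
#' @param out_dir optional directory for `volunteer_report.json` + CSVs.
#' @return report list with `table`, `average_cv`, `friedman`,
#'   `pairwise`, `variance_components`, `power_table`.
#' @export
run_volunteer_workflow <- function(table = NULL, scans = NULL, design = NULL,
                                   site_effects = NULL,
                                   powers = c(0.80, 0.90),
                                   differences = c(5, 10, 20), alpha = 0.05,
                                   out_dir = NULL) {
  supplied <- c(!is.null(table), !is.null(scans), !is.null(design))
  if (sum(supplied) != 1L)
    stop("supply exactly one of `table`, `scans`, `design`")
  if (!is.null(scans)) {
    rows <- lapply(scans, function(sc) {
      vals <- compute_scan_measures(sc$contours, sc$maps,
                                    weight_kg = if (is.null(sc$weight_kg)) NA
                                                else sc$weight_kg,
                                    hepatic = sc$hepatic)
      data.frame(subject = sc$subject, site = sc$site,
                 measure = names(vals), value = unname(vals),
                 stringsAsFactors = FALSE)
    })
    table <- measure_table(do.call(rbind, rows))
  } else if (!is.null(design)) {
    table <- simulate_multisite_study(design, site_effects)$table
  }
  measures <- sort(unique(table$measure))

  cv_rows <- list(); fr_rows <- list(); pw_rows <- list(); vc <- list()
  for (msr in measures) {
    cv <- tryCatch(average_cv(table, msr), error = function(e) e)
    cv_rows[[msr]] <- data.frame(
      measure = msr,
      mean_cv_percent = if (inherits(cv, "error")) NA_real_ else as.numeric(cv),
      n_subjects = if (inherits(cv, "error")) 0L else attr(cv, "n_subjects"),
      note = if (inherits(cv, "error")) conditionMessage(cv) else "",
      stringsAsFactors = FALSE)
    fr <- tryCatch(friedman_across_sites(table, msr), error = function(e) e)
    fr_rows[[msr]] <- data.frame(
      measure = msr,
      statistic = if (inherits(fr, "error")) NA_real_ else fr$statistic,
      p_value = if (inherits(fr, "error")) NA_real_ else fr$p_value,
      n_blocks = if (inherits(fr, "error")) 0L else fr$n_blocks,
      note = if (inherits(fr, "error")) conditionMessage(fr) else "",
      stringsAsFactors = FALSE)
    pw <- tryCatch(pairwise_rank_tests(table, msr), error = function(e) NULL)
    if (!is.null(pw)) { pw$measure <- msr; pw_rows[[msr]] <- pw }
    v <- tryCatch(variance_components(table, msr), error = function(e) NULL)
    if (!is.null(v)) vc[[msr]] <- v
  }
  report <- list(
    workflow = "volunteer",
    table = as.data.frame(table),
    average_cv = do.call(rbind, cv_rows),
    friedman = do.call(rbind, fr_rows),
    pairwise = do.call(rbind, pw_rows),
    variance_components = lapply(vc, function(v)
      list(measure = v$measure, grand_mean = v$grand_mean,
           inter_individual_sd = v$inter_individual_sd,
           inter_assay_sd = v$inter_assay_sd,
           n_subjects = v$n_subjects, n_sites = v$n_sites)),
    power_table = power_table(table, powers = powers,
                              differences = differences, alpha = alpha))
  rownames(report$average_cv) <- rownames(report$friedman) <- NULL
  if (!is.null(report$pairwise)) rownames(report$pairwise) <- NULL
  if (!is.null(out_dir)) write_report(report, out_dir, "volunteer")
  report
}

# Serialize a workflow report deterministically: JSON summary plus CSVs for
# the tabular pieces.
write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, paste0(stem, "_report.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  for (nm in names(report))
    if (is.data.frame(report[[nm]]))
      utils::write.csv(report[[nm]],
                       file.path(out_dir, paste0(stem, "_", nm, ".csv")),
                       row.names = FALSE)
  invisible(out_dir)
}
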