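#' Long-format measure table
#'
#' The substrate of all reproducibility statistics: one row per (subject,
#' site, measure) with a numeric `value` (`NA` = missing, e.g. a map not
#' acquired at that site).  At most one record per cell is allowed; missing
#' cells are dropped pairwise by each statistic, never imputed.
#'
#' @param records data.frame with columns `subject`, `site`, `measure`,
#'   `value`.
#' @return the validated data.frame with class `measure_table`.
#' @export
measure_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("subject", "site", "measure", "value") %in% names(records)))
  records$subject <- as.character(records$subject)
  records$site <- as.character(records$site)
  records$measure <- as.character(records$measure)
  records$value <- as.numeric(records$value)
  key <- paste(records$subject, records$site, records$measure, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, site, measure) record(s): ",
         paste(utils::head(gsub("\r", "/", key[duplicated(key)]), 3),
               collapse = "; "))
  rownames(records) <- NULL
  class(records) <- c("measure_table", "data.frame")
  records
}

# subjects x sites value matrix for one measure, sites with no data dropped
measure_matrix <- function(table, measure, drop_empty_sites = TRUE) {
  stopifnot(inherits(table, "measure_table"))
  d <- table[table$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for measure '", measure, "'")
  subjects <- sort(unique(d$subject))
  sites <- sort(unique(d$site))
  m <- matrix(NA_real_, length(subjects), length(sites),
              dimnames = list(subjects, sites))
  m[cbind(match(d$subject, subjects), match(d$site, sites))] <- d$value
  if (drop_empty_sites) m <- m[, colSums(!is.na(m)) > 0, drop = FALSE]
  m
}

#' Percent difference against a reference value
#'
#' `|measured - reference| / reference * 100`, the accuracy metric for
#' calibrated phantom measurements.
#'
#' @param measured measured value(s).
#' @param reference strictly positive reference value.
#' @return percent difference (non-negative).
#' @export
percent_difference <- function(measured, reference) {
  if (!is.numeric(reference) || any(reference <= 0))
    stop("`reference` must be strictly positive")
  abs(measured - reference) / reference * 100
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the non-missing
#' values, divided by their mean, in percent.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2)
    stop("coefficient of variation needs at least 2 non-missing values, got ",
         length(v))
  m <- mean(v)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(v) / m * 100
}

#' Mean across-site coefficient of variation
#'
#' For each subject, the CV of the measure across the sites where it was
#' obtained; then the unweighted mean over subjects — the headline
#' reproducibility metric of a traveling-volunteer study.  Subjects with
#' fewer than two non-missing sites are excluded with a warning.
#'
#' @param table a [measure_table()].
#' @param measure measure name.
#' @return mean CV in percent, with attribute `per_subject` (named vector)
#'   and `n_subjects`.
#' @export
average_cv <- function(table, measure) {
  m <- measure_matrix(table, measure)
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok < 2))
    warning("subject(s) excluded from '", measure,
            "' CV (fewer than 2 sites): ",
            paste(rownames(m)[n_ok < 2], collapse = ", "))
  m <- m[n_ok >= 2, , drop = FALSE]
  if (nrow(m) == 0) stop("no subject has >= 2 sites for '", measure, "'")
  per <- apply(m, 1, coefficient_of_variation)
  structure(mean(per), per_subject = per, n_subjects = nrow(m))
}

#' Friedman test of a site effect
#'
#' Nonparametric within-subject comparison of a measure across scanners:
#' subjects are blocks, sites are treatments, and the Friedman chi-square is
#' computed on within-subject ranks (chi-square reference with k - 1 df).
#' Sites with no data for the measure are dropped first; subjects missing
#' any remaining site are then excluded block-wise (complete-block design).
#'
#' @param table a [measure_table()].
#' @param measure measure name.
#' @return list with `statistic`, `p_value`, `df`, `n_blocks`, `sites`.
#' @export
friedman_across_sites <- function(table, measure) {
  m <- measure_matrix(table, measure)
  if (ncol(m) < 2) stop("fewer than 2 sites with data for '", measure, "'")
  complete <- stats::complete.cases(m)
  if (sum(complete) < 2)
    stop("fewer than 2 complete blocks for '", measure, "'")
  ft <- stats::friedman.test(m[complete, , drop = FALSE])
  if (is.nan(ft$statistic)) {
    # every block fully tied: the tie correction degenerates to 0/0, but the
    # average-rank statistic is 0 (no site effect whatsoever)
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter), n_blocks = sum(complete),
       sites = colnames(m))
}

#' Pairwise rank tests between sites
#'
#' Wilcoxon tests for every pair of sites on one measure.  The default is
#' the two-sample rank-sum (Mann-Whitney) test as a post-hoc follow-up to
#' [friedman_across_sites()], using the exact null distribution for small
#' tie-free samples and the tie-corrected normal approximation otherwise;
#' `paired = TRUE` switches to the signed-rank test on the subjects common
#' to both sites, which respects the travelling-volunteer pairing.  Raw
#' p-values are reported; set `adjust = "holm"` for a Holm correction.
#'
#' @param table a [measure_table()].
#' @param measure measure name.
#' @param paired use the signed-rank variant (default `FALSE`).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return data.frame with one row per site pair: `site_a`, `site_b`,
#'   `n_a`, `n_b`, `statistic`, `p_value` (`NA` with a note when a pair has
#'   insufficient data).
#' @export
pairwise_rank_tests <- function(table, measure, paired = FALSE,
                                adjust = "none") {
  m <- measure_matrix(table, measure)
  sites <- colnames(m)
  if (length(sites) < 2) stop("fewer than 2 sites with data for '", measure, "'")
  pairs <- utils::combn(sites, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- m[, pairs[1, i]]; b <- m[, pairs[2, i]]
    if (paired) { keep <- !is.na(a) & !is.na(b); a <- a[keep]; b <- b[keep] }
    else { a <- a[!is.na(a)]; b <- b[!is.na(b)] }
    row <- data.frame(site_a = pairs[1, i], site_b = pairs[2, i],
                      n_a = length(a), n_b = length(b),
                      statistic = NA_real_, p_value = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    enough <- if (paired) length(a) >= 2 else (length(a) >= 2 && length(b) >= 2)
    if (!enough) { row$note <- "insufficient data"; return(row) }
    wt <- suppressWarnings(
      if (paired) stats::wilcox.test(a, b, paired = TRUE, exact = NULL)
      else stats::wilcox.test(a, b, exact = NULL))
    row$statistic <- unname(wt$statistic)
    row$p_value <- wt$p.value
    row
  })
  out <- do.call(rbind, res)
  if (adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Inter-individual versus inter-assay variance decomposition
#'
#' The simple mean/SD construction contrasting biological with technical
#' dispersion: the inter-assay (within-subject, between-site) SD is the mean
#' over subjects of each subject's across-site sample SD; the
#' inter-individual (between-subject) SD is the sample SD of the per-subject
#' means; the grand mean is the mean of per-subject means.
#'
#' @param table a [measure_table()].
#' @param measure measure name.
#' @return object of class `variance_components`: list with `measure`,
#'   `grand_mean`, `inter_individual_sd`, `inter_assay_sd`,
#'   `subject_means`, `subject_sds`, `n_subjects`, `n_sites`.
#' @export
variance_components <- function(table, measure) {
  m <- measure_matrix(table, measure)
  n_ok <- rowSums(!is.na(m))
  m <- m[n_ok >= 2, , drop = FALSE]
  if (nrow(m) < 2)
    stop("variance decomposition needs >= 2 subjects with >= 2 sites for '",
         measure, "'")
  subject_means <- apply(m, 1, mean, na.rm = TRUE)
  subject_sds <- apply(m, 1, function(r) stats::sd(r[!is.na(r)]))
  structure(list(measure = measure,
                 grand_mean = mean(subject_means),
                 inter_individual_sd = stats::sd(subject_means),
                 inter_assay_sd = mean(subject_sds),
                 subject_means = subject_means,
                 subject_sds = subject_sds,
                 n_subjects = nrow(m), n_sites = ncol(m)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("<variance_components> %s: grand mean %.4g, ",
                     "inter-individual SD %.4g, inter-assay SD %.4g ",
                     "(%d subjects x %d sites)\n"),
              x$measure, x$grand_mean, x$inter_individual_sd,
              x$inter_assay_sd, x$n_subjects, x$n_sites))
  invisible(x)
}
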