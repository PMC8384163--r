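test_that("measure_table validates records and rejects duplicate cells", {
  d <- data.frame(subject = c("a", "a"), site = c("s1", "s2"),
                  measure = "t1", value = c(1, 2))
  expect_s3_class(measure_table(d), "measure_table")
  dup <- rbind(d, d[1, ])
  expect_error(measure_table(dup), "duplicate")
  expect_error(measure_table(d[, 1:3]), "value")
})

test_that("percent difference against calibrated references", {
  expect_equal(percent_difference(91.2, 89.0), 2.472, tolerance = 1e-3)
  expect_equal(percent_difference(1141, 1000), 14.1)
  expect_equal(percent_difference(89, 89), 0)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("coefficient of variation uses the n-1 SD over non-missing values", {
  expect_equal(coefficient_of_variation(c(676.91, 839.37, 830.25, 707.06)),
               10.932, tolerance = 1e-3)
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  # missing values dropped: result identical to the 3-value computation
  expect_equal(coefficient_of_variation(c(0.40765, 0.28954, 0.34684, NA)),
               coefficient_of_variation(c(0.40765, 0.28954, 0.34684)))
  expect_error(coefficient_of_variation(c(5, NA, NA)), "at least 2")
  # scale invariance
  x <- c(2.3, 3.1, 2.8, 3.3)
  for (k in c(0.1, 7, 1000))
    expect_equal(coefficient_of_variation(k * x), coefficient_of_variation(x))
})

test_that("average CV is the unweighted mean of per-subject across-site CVs", {
  d <- measure_table(data.frame(
    subject = rep(c("a", "b"), each = 3),
    site = rep(c("s1", "s2", "s3"), 2),
    measure = "vol",
    value = c(10, 10, 10, 4, 5, 6)))
  got <- average_cv(d, "vol")
  expect_equal(as.numeric(got), mean(c(0, sd(4:6) / 5 * 100)))
  expect_equal(attr(got, "n_subjects"), 2L)
  # a subject with one site is excluded with a warning
  d2 <- measure_table(rbind(as.data.frame(d), data.frame(
    subject = "c", site = "s1", measure = "vol", value = 9)))
  expect_warning(got2 <- average_cv(d2, "vol"), "excluded")
  expect_equal(as.numeric(got2), as.numeric(got))
})

test_that("Friedman across sites matches a from-scratch rank computation", {
  # identical sites: statistic 0, p 1
  d0 <- expand.grid(subject = letters[1:4], site = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  d0$measure <- "m"; d0$value <- rep(c(5, 7, 6, 9), 3)
  f0 <- friedman_across_sites(measure_table(d0), "m")
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # one site uniformly largest: exact statistic from the textbook formula
  set.seed(17)
  m <- matrix(runif(20), 5, 4)
  m[, 4] <- m[, 4] + 2
  d1 <- measure_table(data.frame(
    subject = rep(paste0("v", 1:5), 4),
    site = rep(paste0("s", 1:4), each = 5),
    measure = "m", value = as.vector(m)))
  f1 <- friedman_across_sites(d1, "m")
  expect_equal(f1$statistic, friedman_oracle(m))
  expect_equal(f1$p_value, pchisq(friedman_oracle(m), 3, lower.tail = FALSE))
  expect_equal(f1$n_blocks, 5)
  # incomplete blocks are dropped, all-missing sites excluded first
  m2 <- m; m2[2, 1] <- NA
  d2 <- d1; d2$value <- as.vector(m2)
  f2 <- friedman_across_sites(measure_table(d2), "m")
  expect_equal(f2$n_blocks, 4)
  expect_equal(f2$statistic, friedman_oracle(m2[-2, ]))
  expect_error(friedman_across_sites(
    measure_table(data.frame(subject = "a", site = "s1", measure = "m",
                             value = 1)), "m"), "sites")
})

test_that("rank-sum p-values match exact enumeration and the null convention", {
  d <- measure_table(data.frame(
    subject = rep(paste0("v", 1:5), 2),
    site = rep(c("s1", "s2"), each = 5),
    measure = "m", value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)))
  pw <- pairwise_rank_tests(d, "m")
  expect_equal(pw$p_value, ranksum_exact_p(1:5, 6:10))
  expect_equal(pw$p_value, 2 / choose(10, 5))
  # identical samples: two-sided p = 1
  d1 <- d; d1$value <- rep(c(3, 1, 4, 1, 5), 2)
  expect_equal(pairwise_rank_tests(measure_table(d1), "m")$p_value, 1)
  # paired variant uses the signed-rank test on common subjects
  dp <- d; dp$value <- c(1, 2, 3, 4, 5, 3, 5, 7, 9, 11)
  pp <- pairwise_rank_tests(measure_table(dp), "m", paired = TRUE)
  expect_equal(pp$p_value, 2 / 2^5)   # all-one-sign exact signed rank, n = 5
  # pairs with insufficient data are flagged, not fatal
  d3 <- measure_table(data.frame(
    subject = c("a", "b", "a"), site = c("s1", "s1", "s2"),
    measure = "m", value = c(1, 2, 3)))
  pw3 <- pairwise_rank_tests(d3, "m")
  expect_true(is.na(pw3$p_value))
  expect_match(pw3$note, "insufficient")
})

test_that("rank tests agree with independent textbook computation on random tables", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(4:8, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    d <- measure_table(data.frame(
      subject = rep(paste0("v", 1:n), k),
      site = rep(paste0("s", 1:k), each = n),
      measure = "m", value = as.vector(m)))
    f <- friedman_across_sites(d, "m")
    expect_equal(f$statistic, friedman_oracle(m), tolerance = 1e-12)
    expect_equal(f$p_value,
                 pchisq(friedman_oracle(m), k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    pw <- pairwise_rank_tests(d, "m")
    first <- pw[1, ]
    expect_equal(first$p_value, ranksum_exact_p(m[, 1], m[, 2]),
                 tolerance = 1e-12)
  }
})

test_that("variance decomposition separates between-subject from between-site spread", {
  # constant table: both SDs zero
  d0 <- measure_table(data.frame(
    subject = rep(c("a", "b"), each = 2), site = rep(c("s1", "s2"), 2),
    measure = "m", value = 5))
  vc0 <- variance_components(d0, "m")
  expect_equal(vc0$inter_individual_sd, 0)
  expect_equal(vc0$inter_assay_sd, 0)
  expect_equal(vc0$grand_mean, 5)
  # hand-checkable 2x2
  d1 <- measure_table(data.frame(
    subject = rep(c("a", "b"), each = 2), site = rep(c("s1", "s2"), 2),
    measure = "m", value = c(10, 12, 20, 26)))
  vc1 <- variance_components(d1, "m")
  expect_equal(vc1$inter_assay_sd, mean(c(sd(c(10, 12)), sd(c(20, 26)))))
  expect_equal(vc1$inter_individual_sd, sd(c(11, 23)))
  expect_error(variance_components(
    measure_table(data.frame(subject = "a", site = c("s1", "s2"),
                             measure = "m", value = 1:2)), "m"), "2 subjects")
})

test_that("with no subject effect, between-subject SD shrinks to site_sd/sqrt(n_sites)", {
  d <- study_design(500, 4, c(m = 100), c(m = 0), c(m = 50), seed = 77)
  vc <- variance_components(simulate_multisite_study(d)$table, "m")
  expect_equal(vc$inter_individual_sd, 50 / sqrt(4), tolerance = 0.1)
})
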