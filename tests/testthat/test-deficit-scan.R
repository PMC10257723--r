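test_that("allele frequencies are counted from phased haplotypes", {
  gt <- matrix(c("0|1", "0|0", "1|1", "0|0"), ncol = 1,
               dimnames = list(NULL, "v1"))
  p <- cohort_panel_from_genotypes(list(pop = gt))
  expect_equal(estimate_population_frequency(p, "v1")$p_hat, 3 / 8)

  all_ref <- matrix(rep("0|0", 6), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
  p2 <- cohort_panel_from_genotypes(list(pop = all_ref))
  expect_equal(estimate_population_frequency(p2, "a")$p_hat, 0)

  # 1000 individuals, 10 heterozygotes + 1 homozygote: 12 / 2000
  gt3 <- matrix(c(rep("0|1", 10), "1|1", rep("0|0", 989)), ncol = 1,
                dimnames = list(NULL, "v1"))
  p3 <- cohort_panel_from_genotypes(list(pop = gt3))
  expect_equal(estimate_population_frequency(p3, "v1")$p_hat, 0.006)

  expect_error(estimate_population_frequency(p, "nope"), "unknown variant")
})

test_that("expected homozygotes sum n_i * p_i^2 across populations", {
  one <- tibble::tibble(population = "all", n = 1.52e6, p_hat = 0.0018135)
  expect_equal(as.numeric(expected_homozygotes(one)), 5.0, tolerance = 1e-3)

  two <- tibble::tibble(population = c("a", "b"), n = c(1000, 1000),
                        p_hat = c(0.1, 0.2))
  lam <- expected_homozygotes(two)
  expect_equal(as.numeric(lam), 50)
  expect_equal(attr(lam, "terms")$lambda_term, c(10, 40))  # additivity, exact

  zero <- tibble::tibble(population = c("a", "b"), n = c(5, 5), p_hat = c(0, 0))
  expect_equal(as.numeric(expected_homozygotes(zero)), 0)
})

test_that("observed homozygotes require the alternate allele on both haplotypes", {
  gt <- matrix(c("0|1", "1|1", "1|1"), ncol = 1, dimnames = list(NULL, "v"))
  p <- cohort_panel_from_genotypes(list(pop = gt))
  expect_equal(as.numeric(observed_homozygotes(p, "v")), 2)

  none <- matrix(rep("0|0", 3), ncol = 1, dimnames = list(NULL, "v"))
  expect_equal(as.numeric(observed_homozygotes(
    cohort_panel_from_genotypes(list(pop = none)), "v")), 0)

  # two populations, one homozygote each
  g1 <- matrix(c("0|1", "1|1", "0|0"), ncol = 1, dimnames = list(NULL, "v"))
  g2 <- matrix(c("1|1", "0|0", "0|1"), ncol = 1, dimnames = list(NULL, "v"))
  o <- observed_homozygotes(cohort_panel_from_genotypes(list(a = g1, b = g2)), "v")
  expect_equal(as.numeric(o), 2)
  expect_equal(attr(o, "by_population")$observed, c(1, 1))
})

test_that("strong deficit means at most 10% of expected, among tested units", {
  r1 <- classify_strong_deficit(1, 29.2)
  expect_equal(r1$ratio, 1 / 29.2, tolerance = 1e-10)  # prints as 0.034
  expect_true(r1$strong_deficit)

  expect_false(classify_strong_deficit(3, 20)$strong_deficit)   # ratio 0.15
  r3 <- classify_strong_deficit(0, 0.4)
  expect_false(r3$tested)          # expected count must exceed 0.5
  expect_false(r3$strong_deficit)
  # inclusive boundary: exactly 10% qualifies
  expect_true(classify_strong_deficit(2, 20)$strong_deficit)
})

test_that("strong-deficit is monotone in observed and expected counts", {
  set.seed(8)
  o <- sample(0:30, 200, replace = TRUE)
  l <- runif(200, 0.6, 50)
  base <- classify_strong_deficit(o, l)$strong_deficit
  fewer <- classify_strong_deficit(pmax(o - 1, 0), l)$strong_deficit
  larger <- classify_strong_deficit(o, l * 1.5)$strong_deficit
  expect_true(all(fewer[base]))    # decreasing O never unsets the flag
  expect_true(all(larger[base]))   # increasing lambda never unsets it
})

test_that("the Poisson deficit p-value is the lower tail", {
  expect_equal(poisson_deficit_pvalue(0, 5), exp(-5))
  expect_equal(poisson_deficit_pvalue(1, 29.2), exp(-29.2) * (1 + 29.2),
               tolerance = 1e-12)
  expect_equal(poisson_deficit_pvalue(1, 29.2), 6.3e-12, tolerance = 0.01)
  expect_gte(poisson_deficit_pvalue(30, 30), 0.5)   # O >= lambda: no deficit
  expect_error(poisson_deficit_pvalue(0, 0), "positive")
})

test_that("Bonferroni thresholds match the published test counts", {
  expect_equal(bonferroni_threshold(1736), 2.9e-5, tolerance = 0.01)
  expect_equal(bonferroni_threshold(1258), 4e-5, tolerance = 0.01)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("MAF inversion of the expected count matches the published thresholds", {
  expect_equal(maf_for_expected_count(5, 1.52e6), 0.0018, tolerance = 0.01)
  expect_equal(maf_for_expected_count(8, 1.52e6), 0.0023, tolerance = 0.01)
  expect_equal(maf_for_expected_count(100, 100), 1)
  expect_error(maf_for_expected_count(0, 10), "positive")
})

test_that("the scan agrees with exhaustive enumeration on small panels", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(5:50, 1)
    freqs <- runif(sample(2:6, 1), 0.05, 0.5)
    gt <- random_gt(n, freqs)
    oracle <- brute_force_scan(gt)
    p <- cohort_panel_from_genotypes(list(pop = gt))
    # small panels can realise p_hat > 0.5 by chance; the exclusion warning
    # is expected and irrelevant to the count comparison
    s <- suppressWarnings(deficit_scan(p))
    s <- s[match(colnames(gt), s$unit_id), ]
    expect_equal(s$lambda, unname(oracle$lambda))
    expect_equal(s$observed, unname(oracle$observed))
  }
})

test_that("scan lambda is exactly additive over populations", {
  p <- cohort_panel_from_genotypes(list(
    a = random_gt(40, c(0.2, 0.4)), b = random_gt(25, c(0.3, 0.1))
  ))
  s <- deficit_scan(p)
  cnt <- panel_counts(p)
  manual <- cnt |>
    dplyr::mutate(term = n_called * (alt_haps / (2 * n_called))^2) |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(lambda = sum(term))
  expect_equal(s$lambda[match(manual$variant_id, s$unit_id)], manual$lambda)
})

test_that("null Poisson p-values are conservative", {
  freqs <- sqrt(seq(1, 25, length.out = 400) / 20000)
  p <- quick_panel(20000, freqs, seed = 51)
  s <- deficit_scan(p)
  for (t in c(0.05, 0.01)) {
    frac <- mean(s$p_poisson < t)
    expect_lte(frac, t + 2 * sqrt(t * (1 - t) / nrow(s)))
  }
})

test_that("variants with alternate frequency above 0.5 are excluded with a warning", {
  gt <- matrix(c(rep("1|1", 8), rep("0|1", 2)), ncol = 1,
               dimnames = list(NULL, "flip"))
  p <- cohort_panel_from_genotypes(list(pop = gt))
  expect_warning(s <- deficit_scan(p), "frequency > 0.5")
  expect_false(s$tested)
})

test_that("inbreeding estimates recover the simulated coefficient", {
  set.seed(60)
  # fully IBD individuals carry no heterozygous sites at all
  p1 <- quick_panel(150, runif(300, 0.1, 0.5), f = 1, seed = 61)
  f1 <- estimate_inbreeding(p1)
  expect_true(all(f1$f_hat == 1))

  # outbred cohort: per-individual estimates centre tightly on zero
  p0 <- quick_panel(300, runif(2000, 0.1, 0.5), f = 0, seed = 62)
  f0 <- estimate_inbreeding(p0)
  expect_lt(abs(mean(f0$f_hat)), 0.01)
  expect_lt(sd(f0$f_hat), 0.05)

  expect_warning(estimate_inbreeding(quick_panel(50, c(0.2, 0.3), seed = 63)),
                 "fewer than 100")
})

test_that("two-proportion power matches the reference implementation and MC", {
  # closed form equals stats::power.prop.test across parameter settings
  for (pars in list(c(1e-5, 1e-6, 1.52e6), c(0.01, 0.001, 5e4),
                    c(0.3, 0.2, 200))) {
    expect_equal(power_two_proportions(pars[1], pars[2], pars[3]),
                 stats::power.prop.test(n = pars[3], p1 = pars[1],
                                        p2 = pars[2])$power,
                 tolerance = 1e-9)
  }
  # null case: equal proportions leave one tail of alpha / 2
  expect_equal(power_two_proportions(0.01, 0.01, 1e4), 0.025, tolerance = 1e-6)
  # inverse consistency
  n <- solve_n_two_proportions(1e-5, 1e-6, 0.05, 0.8)
  expect_equal(power_two_proportions(1e-5, 1e-6, n), 0.8, tolerance = 1e-6)
  # Monte-Carlo rejection rate of the continuity-corrected two-proportion
  # test at the scan's scale
  set.seed(13)
  n0 <- 1.52e6; reps <- 1e4
  x1 <- rbinom(reps, n0, 1e-5); x2 <- rbinom(reps, n0, 1e-6)
  pb <- (x1 + x2) / (2 * n0)
  z <- (abs(x1 - x2) / n0 - 1 / n0) / sqrt(2 * pb * (1 - pb) / n0)
  mc <- mean(z > qnorm(0.975) & x1 > x2)
  expect_equal(power_two_proportions(1e-5, 1e-6, n0), mc, tolerance = 0.02)
  expect_error(power_two_proportions(0, 0.1, 10), "inside")
})
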