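#' Estimate per-population allele frequencies for one variant
#'
#' The frequency estimate is the alternate haplotype count divided by twice
#' the number of genotyped individuals. For the rare variants this scan
#' targets, the estimate is driven by non-carriers and heterozygotes and is
#' only marginally affected by the (possibly depleted) homozygotes — which is
#' what makes the expected homozygote count a usable yardstick.
#'
#' @param panel A [new_cohort_panel()] object.
#' @param variant_id Variant identifier present in the panel.
#' @return A tibble with one row per population: `population`, `n`
#'   (individuals genotyped for the variant), `alt_haps`, `p_hat`.
#' @examples
#' gt <- matrix(c("0|1", "0|0", "1|1", "0|0"), ncol = 1,
#'              dimnames = list(NULL, "v1"))
#' p <- cohort_panel_from_genotypes(list(pop = gt))
#' estimate_population_frequency(p, "v1")  # p_hat = 3/8
#' @export
estimate_population_frequency <- function(panel, variant_id) {
  stopifnot(inherits(panel, "cohort_panel"), length(variant_id) == 1)
  if (!variant_id %in% panel$variants$variant_id) {
    stop("unknown variant_id: ", variant_id, call. = FALSE)
  }
  panel_counts(panel) |>
    dplyr::filter(.data$variant_id == .env$variant_id) |>
    dplyr::transmute(
      population = .data$population,
      n = .data$n_called,
      alt_haps = .data$alt_haps,
      p_hat = ifelse(.data$n > 0, .data$alt_haps / (2 * .data$n), 0)
    )
}

#' Expected homozygote count under Hardy-Weinberg equilibrium
#'
#' Within population `i`, `n_i * p_i^2` homozygotes are expected under HWE;
#' the combined expectation is the sum over populations,
#' `lambda = sum_i n_i * p_i^2`. Populations where the variant is absent
#' contribute 0.
#'
#' @param freqs A tibble with columns `population`, `n` and `p_hat`, as
#'   returned by [estimate_population_frequency()].
#' @return The combined expected count `lambda` (a scalar), with the
#'   per-population terms attached as attribute `"terms"`.
#' @examples
#' expected_homozygotes(tibble::tibble(
#'   population = c("a", "b"), n = c(1000, 1000), p_hat = c(0.1, 0.2)
#' ))  # 10 + 40 = 50
#' @export
expected_homozygotes <- function(freqs) {
  stopifnot(all(c("population", "n", "p_hat") %in% names(freqs)))
  if (any(freqs$p_hat < 0 | freqs$p_hat > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  terms <- freqs |>
    dplyr::mutate(lambda_term = .data$n * .data$p_hat^2) |>
    dplyr::select("population", "n", "p_hat", "lambda_term")
  lambda <- sum(terms$lambda_term)
  attr(lambda, "terms") <- terms
  lambda
}

#' Observed homozygote count for one variant
#'
#' @inheritParams estimate_population_frequency
#' @return Combined count of individuals carrying the alternate allele on
#'   both haplotypes, with per-population counts as attribute
#'   `"by_population"`.
#' @export
observed_homozygotes <- function(panel, variant_id) {
  stopifnot(inherits(panel, "cohort_panel"), length(variant_id) == 1)
  if (!variant_id %in% panel$variants$variant_id) {
    stop("unknown variant_id: ", variant_id, call. = FALSE)
  }
  by_pop <- panel_counts(panel) |>
    dplyr::filter(.data$variant_id == .env$variant_id) |>
    dplyr::select("population", observed = "hom")
  out <- sum(by_pop$observed)
  attr(out, "by_population") <- by_pop
  out
}

#' Classify strong deficits of homozygosity
#'
#' A unit (variant or gene) is *tested* when its expected homozygote count
#' exceeds 0.5, and shows a *strong deficit* when the observed count is 10%
#' or less of the expected count (`observed <= deficit_ratio * lambda`). The
#' inclusive boundary follows the headline definition "10% or less of
#' predicted homozygotes".
#'
#' @param observed Non-negative integer vector of observed homozygotes.
#' @param lambda Non-negative vector of expected homozygotes.
#' @param deficit_ratio Deficit threshold on `observed / lambda`; default 0.1.
#' @param min_lambda Minimum expected count for a unit to be tested;
#'   default 0.5.
#' @return A tibble with columns `ratio`, `tested`, `strong_deficit`.
#' @examples
#' classify_strong_deficit(observed = 1, lambda = 29.2)   # strong
#' classify_strong_deficit(observed = 3, lambda = 20)     # not strong
#' classify_strong_deficit(observed = 0, lambda = 0.4)    # not tested
#' @export
classify_strong_deficit <- function(observed, lambda, deficit_ratio = 0.1,
                                    min_lambda = 0.5) {
  stopifnot(all(observed >= 0), all(lambda >= 0))
  tested <- lambda > min_lambda
  tibble::tibble(
    ratio = ifelse(lambda > 0, observed / lambda, NA_real_),
    tested = tested,
    strong_deficit = tested & observed <= deficit_ratio * lambda
  )
}

#' One-sided Poisson test for a homozygote deficit
#'
#' For rare variants the observed homozygote count is approximately Poisson
#' with mean `lambda`; the deficit p-value is the lower tail
#' `P(X <= observed)`.
#'
#' @inheritParams classify_strong_deficit
#' @return Vector of one-sided lower-tail p-values.
#' @examples
#' poisson_deficit_pvalue(0, 5)      # exp(-5)
#' poisson_deficit_pvalue(1, 29.2)   # ~6.3e-12
#' @export
poisson_deficit_pvalue <- function(observed, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  stopifnot(all(observed >= 0))
  stats::ppois(observed, lambda)
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests performed (>= 1).
#' @param alpha Family-wise error rate; default 0.05.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(1736)  # 2.9e-5
#' bonferroni_threshold(1258)  # 4e-5
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (any(n_tests < 1)) stop("n_tests must be at least 1", call. = FALSE)
  alpha / n_tests
}

#' Minor allele frequency corresponding to an expected homozygote count
#'
#' Inverts `lambda = n * p^2` for a single pooled cohort: the MAF at which
#' `E` homozygotes are expected among `total_n` individuals.
#'
#' @param expected Expected homozygote count (> 0).
#' @param total_n Cohort size (> 0).
#' @return `sqrt(expected / total_n)`.
#' @examples
#' maf_for_expected_count(5, 1.52e6)  # 0.0018 (0.18%)
#' maf_for_expected_count(8, 1.52e6)  # 0.0023 (0.23%)
#' @export
maf_for_expected_count <- function(expected, total_n) {
  if (any(expected <= 0) || any(total_n <= 0)) {
    stop("expected count and cohort size must be positive", call. = FALSE)
  }
  sqrt(expected / total_n)
}

#' Scan a panel for deficits of homozygosity
#'
#' Runs the full single-unit scan over every variant in the panel:
#' per-population frequency estimation, expected homozygotes under HWE
#' summed across populations, observed homozygotes, strong-deficit
#' classification and the one-sided Poisson p-value. Variants whose pooled
#' alternate allele frequency exceeds 0.5 are excluded from testing with a
#' warning (the scan targets rare alleles and `p_hat^2` would then track the
#' major allele).
#'
#' @inheritParams classify_strong_deficit
#' @param panel A [new_cohort_panel()] object.
#' @return A tibble with one row per variant: `unit_id`, `impact_class`,
#'   `gene`, `maf` (pooled alternate frequency), `lambda`, `observed`,
#'   `ratio`, `tested`, `strong_deficit`, `p_poisson`.
#' @export
deficit_scan <- function(panel, deficit_ratio = 0.1, min_lambda = 0.5) {
  stopifnot(inherits(panel, "cohort_panel"))
  counts <- panel_counts(panel)
  per_unit <- counts |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      maf = sum(.data$alt_haps) / pmax(2 * sum(.data$n_called), 1),
      lambda = sum(ifelse(.data$n_called > 0,
                          .data$n_called * (.data$alt_haps / (2 * .data$n_called))^2, 0)),
      observed = sum(.data$hom),
      .groups = "drop"
    )
  meta <- panel$variants |>
    dplyr::select(dplyr::any_of(c("variant_id", "impact_class", "gene")))
  out <- per_unit |>
    dplyr::left_join(meta, by = "variant_id") |>
    dplyr::rename(unit_id = "variant_id")
  cls <- classify_strong_deficit(out$observed, out$lambda,
                                 deficit_ratio = deficit_ratio,
                                 min_lambda = min_lambda)
  out <- dplyr::bind_cols(out, cls)
  high_maf <- out$maf > 0.5
  if (any(high_maf)) {
    warning(sum(high_maf), " variant(s) with alternate allele frequency > 0.5 ",
            "excluded from deficit testing", call. = FALSE)
    out$tested[high_maf] <- FALSE
    out$strong_deficit[high_maf] <- FALSE
  }
  out$p_poisson <- ifelse(out$lambda > 0,
                          stats::ppois(out$observed, out$lambda), NA_real_)
  cols <- c("unit_id", "impact_class", "gene", "maf", "lambda", "observed",
            "ratio", "tested", "strong_deficit", "p_poisson")
  out[, intersect(cols, names(out))]
}

#' Per-individual inbreeding coefficients from heterozygosity
#'
#' Method-of-moments estimator: `f_hat = 1 - observed heterozygous sites /
#' expected heterozygous sites`, where the expectation is `sum_j 2 p_j q_j`
#' over variants polymorphic in the individual's population. Outbred
#' individuals give `f_hat ~ 0`; an individual whose two haplotypes are
#' identical by descent genome-wide has no heterozygous sites and `f_hat = 1`.
#'
#' @param panel A [new_cohort_panel()] object. At least one polymorphic
#'   variant per population is required; fewer than 100 triggers a warning
#'   since the estimator is noisy.
#' @return A tibble: `population`, `individual`, `n_het`, `expected_het`,
#'   `f_hat`.
#' @export
estimate_inbreeding <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  purrr::map_dfr(panel$populations, function(pop) {
    a <- .hap_a(pop$haps); b <- .hap_b(pop$haps)
    p <- (Matrix::colSums(a) + Matrix::colSums(b)) / (2 * pop$n)
    poly <- p > 0 & p < 1
    if (!any(poly)) {
      stop("no polymorphic variants in population '", pop$name, "'", call. = FALSE)
    }
    if (sum(poly) < 100) {
      warning("fewer than 100 polymorphic variants in population '", pop$name,
              "'; inbreeding estimates will be noisy", call. = FALSE)
    }
    a <- a[, poly, drop = FALSE]; b <- b[, poly, drop = FALSE]
    n_het <- Matrix::rowSums(a) + Matrix::rowSums(b) - 2 * Matrix::rowSums(a * b)
    e_het <- sum(2 * p[poly] * (1 - p[poly]))
    tibble::tibble(
      population = pop$name,
      individual = pop$individuals %||% sprintf("%s_%04d", pop$name, seq_len(pop$n)),
      n_het = as.numeric(n_het),
      expected_het = e_het,
      f_hat = 1 - n_het / e_het
    )
  })
}
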