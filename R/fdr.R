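#' Expected-count bin edges for FDR calibration
#'
#' The half-open bins used to group tested units by their expected
#' homozygote count: `[0.5,1) [1,2) [2,3) [3,5) [5,8) [8,13) [13,250)
#' [250,Inf)`.
#'
#' @return Numeric vector of bin edges.
#' @export
fdr_bin_edges <- function() c(0.5, 1, 2, 3, 5, 8, 13, 250, Inf)

bin_labels <- function(edges) {
  lo <- utils::head(edges, -1)
  hi <- utils::tail(edges, -1)
  sprintf("[%g,%g)", lo, hi)
}

#' Assign expected counts to half-open bins
#'
#' @param lambda Expected homozygote counts; all must exceed 0.5 (untested
#'   units are rejected).
#' @param edges Bin edges; default [fdr_bin_edges()].
#' @return Factor of bin labels (levels in bin order).
#' @examples
#' bin_by_expected_count(c(0.9, 5, 300))
#' @export
bin_by_expected_count <- function(lambda, edges = fdr_bin_edges()) {
  if (any(lambda <= 0.5)) {
    stop("lambda <= 0.5: only tested units (expected count > 0.5) are binned",
         call. = FALSE)
  }
  labs <- bin_labels(edges)
  idx <- findInterval(lambda, edges)
  factor(labs[idx], levels = labs)
}

#' Fraction of units with a strong deficit
#'
#' @param results Tibble with a logical `strong_deficit` column (one row per
#'   tested unit).
#' @return A one-row tibble: `n_deficit`, `n_tested`, `fraction`. An empty
#'   input yields `n_tested = 0` and `fraction = NA` (unavailable, not zero).
#' @export
deficit_fraction <- function(results) {
  n <- nrow(results)
  x <- sum(results$strong_deficit)
  tibble::tibble(
    n_deficit = x,
    n_tested = n,
    fraction = if (n > 0) x / n else NA_real_
  )
}

#' Empirical FDR from class-wise deficit fractions
#'
#' The false discovery rate of the strong-deficit call among protein-altering
#' variants is estimated as the ratio of deficit fractions,
#' `FDR = f_intergenic / f_pav`, under the assumption that homozygosity for
#' intergenic variants is effectively neutral; `PPV = 1 - FDR`.
#'
#' @param f_intergenic,f_pav Deficit fractions in the reference (intergenic)
#'   and target class.
#' @return A one-row tibble: `fdr` (uncapped), `fdr_capped` (display value,
#'   at most 1), `ppv`. `f_pav = 0` or `NA` yields `NA` throughout.
#' @examples
#' compute_fdr(0.002, 0.04)  # FDR 0.05, PPV 0.95
#' @export
compute_fdr <- function(f_intergenic, f_pav) {
  fdr <- ifelse(!is.na(f_pav) & f_pav > 0, f_intergenic / f_pav, NA_real_)
  tibble::tibble(fdr = fdr, fdr_capped = pmin(fdr, 1), ppv = 1 - fdr)
}

#' Exact confidence interval for a ratio of Poisson rates
#'
#' Treats `x1 ~ Poisson(n1 * r1)` and `x2 ~ Poisson(n2 * r2)` as independent
#' and estimates a CI for `r1 / r2`. Conditional on `x1 + x2`, `x1` is
#' binomial with success probability `theta = n1 r1 / (n1 r1 + n2 r2)`; an
#' exact Clopper-Pearson interval for `theta` is mapped through
#' `theta / (1 - theta) * (n2 / n1)`. This is the package's implementation of
#' an approximate-estimate CI for two Poisson rates; the method name travels
#' with the result so downstream output records how the interval was formed.
#'
#' @param x1,x2 Non-negative event counts.
#' @param n1,n2 Positive exposures (here: numbers of tested variants).
#' @param level Confidence level; default 0.95.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `method`.
#'   Both counts zero yields `NA` bounds with a warning.
#' @export
rate_ratio_ci <- function(x1, n1, x2, n2, level = 0.95) {
  stopifnot(x1 >= 0, x2 >= 0, n1 > 0, n2 > 0, level > 0, level < 1)
  est <- if (x2 > 0) (x1 / n1) / (x2 / n2) else NA_real_
  if (x1 + x2 == 0) {
    warning("both counts are zero: rate ratio CI unavailable", call. = FALSE)
    return(tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_,
                          method = "conditional-binomial exact"))
  }
  ci_theta <- stats::binom.test(x1, x1 + x2, conf.level = level)$conf.int
  to_ratio <- function(theta) {
    if (theta >= 1) return(Inf)
    theta / (1 - theta) * (n2 / n1)
  }
  tibble::tibble(
    estimate = est,
    conf_low = to_ratio(ci_theta[1]),
    conf_high = to_ratio(ci_theta[2]),
    method = "conditional-binomial exact"
  )
}

#' Calibrate the strong-deficit FDR against intergenic variants
#'
#' Bins tested units by expected homozygote count, computes per-class deficit
#' fractions within each bin, and estimates `FDR = f_reference / f_class`
#' with an exact rate-ratio confidence interval (see [rate_ratio_ci()]).
#'
#' @param results Scan output ([deficit_scan()] or [genelof_deficit_scan()]
#'   rows, possibly concatenated) containing `lambda`, `tested`,
#'   `strong_deficit` and a class column.
#' @param class_col Name of the class column; default `"impact_class"`.
#' @param reference Neutral reference class; default `"intergenic"`.
#' @param classes Target classes to calibrate; default all non-reference
#'   classes present.
#' @param edges Bin edges; default [fdr_bin_edges()].
#' @param level Confidence level for the FDR interval.
#' @return A tibble of class `lethalscan_fdr`, one row per (class, bin):
#'   counts and fractions for the class and the reference, `fdr`,
#'   `fdr_capped`, `ppv` and the CI. Bins empty in either class carry `NA`
#'   fractions (flagged unavailable, not zero).
#' @export
fdr_calibrate <- function(results, class_col = "impact_class",
                          reference = "intergenic", classes = NULL,
                          edges = fdr_bin_edges(), level = 0.95) {
  stopifnot(all(c("lambda", "tested", "strong_deficit") %in% names(results)),
            class_col %in% names(results))
  tested <- results[results$tested, , drop = FALSE]
  tested$.bin <- bin_by_expected_count(tested$lambda, edges)
  tested$.class <- tested[[class_col]]
  if (!reference %in% tested$.class) {
    stop("reference class '", reference, "' has no tested units", call. = FALSE)
  }
  if (is.null(classes)) classes <- setdiff(unique(tested$.class), reference)
  labs <- levels(tested$.bin)
  lo <- utils::head(edges, -1); hi <- utils::tail(edges, -1)
  ref_tab <- tested |>
    dplyr::filter(.data$.class == reference) |>
    dplyr::group_by(.bin = .data$.bin) |>
    dplyr::summarise(ref_deficit = sum(.data$strong_deficit),
                     ref_tested = dplyr::n(), .groups = "drop")
  out <- purrr::map_dfr(classes, function(cl) {
    cl_tab <- tested |>
      dplyr::filter(.data$.class == cl) |>
      dplyr::group_by(.bin = .data$.bin) |>
      dplyr::summarise(n_deficit = sum(.data$strong_deficit),
                       n_tested = dplyr::n(), .groups = "drop")
    grid <- tibble::tibble(.bin = factor(labs, levels = labs),
                           lo = lo, hi = hi, class = cl) |>
      dplyr::left_join(cl_tab, by = ".bin") |>
      dplyr::left_join(ref_tab, by = ".bin") |>
      dplyr::mutate(dplyr::across(c("n_deficit", "n_tested",
                                    "ref_deficit", "ref_tested"),
                                  ~ tidyr::replace_na(.x, 0L)))
    grid |>
      dplyr::mutate(
        fraction = ifelse(.data$n_tested > 0,
                          .data$n_deficit / .data$n_tested, NA_real_),
        ref_fraction = ifelse(.data$ref_tested > 0,
                              .data$ref_deficit / .data$ref_tested, NA_real_)
      ) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        fdr_tbl = list(compute_fdr(.data$ref_fraction, .data$fraction)),
        ci_tbl = list(
          if (.data$n_tested > 0 && .data$ref_tested > 0 &&
              .data$ref_deficit + .data$n_deficit > 0 && .data$n_deficit > 0) {
            rate_ratio_ci(.data$ref_deficit, .data$ref_tested,
                          .data$n_deficit, .data$n_tested, level = level)[
                            , c("conf_low", "conf_high", "method")]
          } else {
            tibble::tibble(conf_low = NA_real_, conf_high = NA_real_,
                           method = "conditional-binomial exact")
          }
        )
      ) |>
      dplyr::ungroup() |>
      tidyr::unnest(c("fdr_tbl", "ci_tbl"))
  })
  out <- out |>
    dplyr::rename(bin = ".bin") |>
    dplyr::relocate("class", "bin", "lo", "hi")
  class(out) <- c("lethalscan_fdr", class(out))
  out
}

#' Plot the calibrated FDR by expected-count bin
#'
#' @param object A [fdr_calibrate()] result.
#' @param ... Unused.
#' @return A ggplot: capped FDR per bin with exact CIs, faceted by class.
#' @export
autoplot.lethalscan_fdr <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$fdr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$fdr_capped)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmin(.data$conf_low, 1), ymax = pmin(.data$conf_high, 1)),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "expected homozygote count bin",
                  y = "FDR (capped at 1)",
                  title = "Strong-deficit FDR relative to intergenic variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
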