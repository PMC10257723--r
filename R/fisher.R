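#' Fisher's exact test for a 2x2 table with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 contingency table: the two-sided p-value sums
#' the probabilities of all tables (under the null, conditional on the
#' margins) no more probable than the observed one; the odds ratio estimate
#' is the conditional maximum-likelihood value, i.e. the noncentrality
#' parameter psi at which the expected top-left cell under the noncentral
#' hypergeometric distribution equals the observed count, solved here to a
#' score-equation residual below 1e-8; the confidence interval inverts the
#' exact conditional tails. The p-value and CI are delegated to
#' [stats::fisher.test()]; the test-suite verifies both against a direct
#' enumeration of the hypergeometric support.
#'
#' @param table A 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given separately. Rows are the condition
#'   (e.g. strong deficit yes/no), columns the outcome (e.g. in gene set
#'   yes/no).
#' @param b,c,d Optional remaining cell counts (row-wise).
#' @param level Confidence level; default 0.95.
#' @return An object of class `lethalscan_fisher` with fields `table`,
#'   `estimate` (conditional-MLE odds ratio), `conf_low`, `conf_high`,
#'   `p_value`, `level`. Degenerate margins (an empty row or column) give
#'   `p_value = 1` and an `NA` odds ratio. Use [tidy()] for a tibble.
#' @examples
#' fisher_exact_2x2(matrix(c(11, 8, 85, 942), nrow = 2))  # OR ~ 15.1
#' tidy(fisher_exact_2x2(2, 1, 1, 2))                     # p = 1, OR ~ 3.1
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                             level = 0.95) {
  if (!is.null(b)) {
    table <- matrix(c(table, c, b, d), nrow = 2)
  }
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  storage.mode(table) <- "integer"
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (degenerate) {
    res <- list(table = table, estimate = NA_real_, conf_low = NA_real_,
                conf_high = NA_real_, p_value = 1, level = level)
  } else {
    ft <- stats::fisher.test(table, conf.level = level)
    res <- list(table = table,
                estimate = cmle_odds_ratio(table[1, 1], table[1, 2],
                                           table[2, 1], table[2, 2]),
                conf_low = ft$conf.int[1], conf_high = ft$conf.int[2],
                p_value = ft$p.value, level = level)
  }
  structure(res, class = "lethalscan_fisher")
}

# Conditional-MLE odds ratio: solve E_psi[a | margins] = a on the log scale.
# Observed count at the edge of the conditional support gives 0 / Inf.
cmle_odds_ratio <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  s <- max(0, k - n2):min(k, m)
  if (length(s) == 1) return(NA_real_)
  if (a == min(s)) return(0)
  if (a == max(s)) return(Inf)
  lw0 <- stats::dhyper(s, m, n2, k, log = TRUE)
  score <- function(log_psi) {
    lw <- lw0 + s * log_psi
    w <- exp(lw - max(lw))
    sum(s * w) / sum(w) - a
  }
  lo <- -1; hi <- 1
  while (score(lo) > 0) lo <- lo * 2
  while (score(hi) < 0) hi <- hi * 2
  exp(stats::uniroot(score, c(lo, hi), tol = 1e-12)$root)
}

#' @export
print.lethalscan_fisher <- function(x, ...) {
  cat("<fisher 2x2> OR =", format(x$estimate, digits = 3),
      sprintf("[%d%% CI %s-%s], p = %s\n", round(100 * x$level),
              format(x$conf_low, digits = 3), format(x$conf_high, digits = 3),
              format(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
tidy.lethalscan_fisher <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$conf_low,
                 conf.high = x$conf_high, p.value = x$p_value)
}

#' @export
glance.lethalscan_fisher <- function(x, ...) {
  dplyr::mutate(tidy(x), conf.level = x$level,
                method = "Fisher exact (conditional MLE)")
}

#' Gene-set over-representation among deficit genes, by expected-count bin
#'
#' For each gene set and each expected-count stratum, builds the 2x2 table
#' of (strong deficit vs not) x (in set vs not) over tested genes in the
#' stratum and applies [fisher_exact_2x2()]. The default strata separate
#' genes with one-to-five expected knockouts from those with five or more,
#' where the scan is well powered.
#'
#' @param gene_results A gene-level scan ([genelof_deficit_scan()]) with
#'   `unit_id`, `lambda`, `tested`, `strong_deficit`.
#' @param gene_sets Tibble of memberships: `gene`, `set`.
#' @param bins Stratum edges on the expected count; default `c(1, 5, Inf)`.
#' @param level Confidence level.
#' @return A tibble with one row per (set, bin): the four cell counts
#'   (`a` deficit-in-set, `b` no-deficit-in-set, `c` deficit-not-in-set,
#'   `d` no-deficit-not-in-set), `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, and `empty_stratum` flagging strata without tested genes.
#' @export
overrepresentation_by_bin <- function(gene_results, gene_sets,
                                      bins = c(1, 5, Inf), level = 0.95) {
  stopifnot(all(c("unit_id", "lambda", "tested", "strong_deficit")
                %in% names(gene_results)),
            all(c("gene", "set") %in% names(gene_sets)))
  genes <- gene_results[gene_results$tested & gene_results$lambda >= bins[1], ,
                        drop = FALSE]
  labs <- bin_labels(bins)
  genes$.bin <- factor(labs[findInterval(genes$lambda, bins)], levels = labs)
  purrr::map_dfr(unique(gene_sets$set), function(s) {
    members <- gene_sets$gene[gene_sets$set == s]
    purrr::map_dfr(labs, function(bl) {
      g <- genes[genes$.bin == bl, , drop = FALSE]
      if (!nrow(g)) {
        return(tibble::tibble(set = s, bin = bl, a = 0L, b = 0L, c = 0L,
                              d = 0L, estimate = NA_real_,
                              conf.low = NA_real_, conf.high = NA_real_,
                              p.value = NA_real_, empty_stratum = TRUE))
      }
      in_set <- g$unit_id %in% members
      tab <- matrix(c(sum(g$strong_deficit & in_set),
                      sum(!g$strong_deficit & in_set),
                      sum(g$strong_deficit & !in_set),
                      sum(!g$strong_deficit & !in_set)), nrow = 2,
                    byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      tibble::tibble(set = s, bin = bl,
                     a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
                     estimate = ft$estimate, conf.low = ft$conf_low,
                     conf.high = ft$conf_high, p.value = ft$p_value,
                     empty_stratum = FALSE)
    })
  })
}
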