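#' Identify carrier couples for each gene
#'
#' A carrier couple for a gene has both partners heterozygous
#' (`haplotypes_affected == 1`) for a qualifying pLOF of that gene; each of
#' their pregnancies has a one-in-four chance of a homozygous conception.
#' Couples where a partner is themselves homozygous (both haplotypes
#' affected) are not heterozygous carrier couples and are excluded from the
#' `"both"` category with a message.
#'
#' @param genelof A [collapse_to_genelof()] result.
#' @param couples Tibble of couples: `couple_id`, `mother`, `father`, plus
#'   any covariates (carried through).
#' @param individuals Character vector of genotyped individual ids; couples
#'   with an ungenotyped partner are dropped with a message.
#' @param genes Genes to assess; default all genes in `genelof`.
#' @return A tibble with one row per (couple, gene):
#'   the couple's columns plus `gene` and `carrier_status`
#'   (`"both"`, `"one"`, `"neither"`, or `"excluded_homozygote"`).
#' @export
identify_carrier_couples <- function(genelof, couples, individuals,
                                     genes = NULL) {
  stopifnot(all(c("couple_id", "mother", "father") %in% names(couples)))
  if (is.null(genes)) genes <- sort(unique(genelof$gene))
  genotyped <- couples$mother %in% individuals & couples$father %in% individuals
  if (any(!genotyped)) {
    message(sum(!genotyped), " couple(s) dropped: partner not genotyped")
    couples <- couples[genotyped, , drop = FALSE]
  }
  aff <- genelof[genelof$gene %in% genes,
                 c("individual", "gene", "haplotypes_affected")]
  out <- tidyr::crossing(couples, gene = genes) |>
    dplyr::left_join(aff, by = c(mother = "individual", "gene")) |>
    dplyr::rename(aff_mother = "haplotypes_affected") |>
    dplyr::left_join(aff, by = c(father = "individual", "gene")) |>
    dplyr::rename(aff_father = "haplotypes_affected") |>
    dplyr::mutate(
      aff_mother = tidyr::replace_na(.data$aff_mother, 0L),
      aff_father = tidyr::replace_na(.data$aff_father, 0L),
      carrier_status = dplyr::case_when(
        aff_mother == 2L | aff_father == 2L ~ "excluded_homozygote",
        aff_mother == 1L & aff_father == 1L ~ "both",
        aff_mother >= 1L | aff_father >= 1L ~ "one",
        TRUE ~ "neither"
      )
    )
  n_hom <- sum(out$carrier_status == "excluded_homozygote")
  if (n_hom > 0) {
    message(n_hom, " couple-gene pair(s) excluded: a partner is homozygous, ",
            "not a heterozygous carrier")
  }
  dplyr::select(out, -"aff_mother", -"aff_father")
}

#' Nearest-neighbour matched control couples
#'
#' Matches each case couple to the `ratio` nearest control couples (1:100 by
#' default, with replacement across cases) by Euclidean distance on
#' covariates standardised by the pool standard deviation. Ties are broken
#' by couple id, so the match is deterministic; the seed is only consumed in
#' the degenerate situation where the pool is smaller than `ratio` and
#' controls must be resampled with replacement.
#'
#' @param cases,pool Tibbles of couples carrying `couple_id` and the matching
#'   covariates. The pool should contain non-carrier (`"neither"`) couples.
#' @param ratio Controls per case; default 100.
#' @param covariates Matching covariates; default mother's birth year and
#'   number of pregnancies.
#' @param seed Seed for the degenerate resampling path.
#' @return A tibble of matched controls: `case_couple_id`, `match_distance`,
#'   plus all pool columns. Each case contributes exactly `ratio` rows.
#' @export
match_control_couples <- function(cases, pool, ratio = 100,
                                  covariates = c("birth_year", "n_pregnancies"),
                                  seed = 1L) {
  stopifnot(nrow(cases) > 0, all(covariates %in% names(cases)),
            all(covariates %in% names(pool)), "couple_id" %in% names(pool))
  if (nrow(pool) == 0) stop("empty control pool", call. = FALSE)
  sds <- vapply(pool[covariates], stats::sd, numeric(1))
  sds[is.na(sds) | sds == 0] <- 1  # constant covariate: no contribution
  zp <- sweep(as.matrix(pool[covariates]), 2, sds, "/")
  zc <- sweep(as.matrix(cases[covariates]), 2, sds, "/")
  short <- nrow(pool) < ratio
  if (short) {
    warning("control pool (", nrow(pool), ") smaller than matching ratio (",
            ratio, "); sampling with replacement", call. = FALSE)
    set.seed(seed)
  }
  ord_pool <- order(pool$couple_id)
  purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    d <- sqrt(colSums((t(zp) - zc[i, ])^2))
    o <- order(d[ord_pool])  # stable: pool pre-sorted by couple_id
    take <- ord_pool[o][seq_len(min(ratio, nrow(pool)))]
    if (short) take <- sample(take, ratio, replace = TRUE)
    dplyr::bind_cols(
      tibble::tibble(case_couple_id = cases$couple_id[i],
                     match_distance = d[take]),
      pool[take, , drop = FALSE]
    )
  })
}

couple_outcome_table <- function(cases, controls, what = c("ever", "pregnancy")) {
  what <- match.arg(what)
  if (what == "ever") {
    stopifnot("ever_miscarriage" %in% names(cases),
              "ever_miscarriage" %in% names(controls))
    matrix(c(sum(cases$ever_miscarriage), sum(!cases$ever_miscarriage),
             sum(controls$ever_miscarriage), sum(!controls$ever_miscarriage)),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("case", "control"), c("ever", "never")))
  } else {
    stopifnot(all(c("n_pregnancies", "n_miscarriages") %in% names(cases)),
              all(c("n_pregnancies", "n_miscarriages") %in% names(controls)))
    if (sum(cases$n_pregnancies) == 0 || sum(controls$n_pregnancies) == 0) {
      stop("an arm has zero pregnancies", call. = FALSE)
    }
    matrix(c(sum(cases$n_miscarriages),
             sum(cases$n_pregnancies) - sum(cases$n_miscarriages),
             sum(controls$n_miscarriages),
             sum(controls$n_pregnancies) - sum(controls$n_miscarriages)),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("case", "control"),
                           c("miscarriage", "no_miscarriage")))
  }
}

#' Miscarriage-ever excess among carrier couples
#'
#' Tests whether mothers from carrier couples are more likely to have ever
#' experienced a miscarriage than matched control mothers, with a 2x2
#' Fisher exact test of (case/control) x (ever miscarried yes/no).
#'
#' @param cases Carrier couples (with `ever_miscarriage`).
#' @param controls Matched control couples (see [match_control_couples()]).
#' @param level Confidence level.
#' @return A [fisher_exact_2x2()] result; the 2x2 table is in `$table`.
#' @export
miscarriage_ever_test <- function(cases, controls, level = 0.95) {
  if (!nrow(cases) || !nrow(controls)) stop("empty arm", call. = FALSE)
  fisher_exact_2x2(couple_outcome_table(cases, controls, "ever"), level = level)
}

#' Per-pregnancy miscarriage excess among carrier couples
#'
#' Pools pregnancies within each arm and tests the 2x2 of (case/control) x
#' (pregnancy ended in miscarriage yes/no).
#'
#' @inheritParams miscarriage_ever_test
#' @return A [fisher_exact_2x2()] result.
#' @export
miscarriage_per_pregnancy_test <- function(cases, controls, level = 0.95) {
  if (!nrow(cases) || !nrow(controls)) stop("empty arm", call. = FALSE)
  fisher_exact_2x2(couple_outcome_table(cases, controls, "pregnancy"),
                   level = level)
}
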