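#' Select pLOF variants that qualify for gene collapsing
#'
#' A predicted loss-of-function variant qualifies when it is
#' high-confidence, its minor allele frequency is below the threshold
#' (default 2%, applied per population: founder populations can carry
#' pathogenic alleles at elevated frequencies, so each cohort is assessed
#' with its own frequencies), and it is not on the curated exclusion list of
#' ids flagged as likely not loss-of-function.
#'
#' @param variants Variant table with `variant_id`, `impact_class`, `gene`
#'   and `plof_confidence`.
#' @param freqs Tibble of per-population frequencies: `variant_id`,
#'   `population`, `p_hat` (see [panel_frequencies()]).
#' @param maf_max MAF upper bound; default 0.02.
#' @param exclude_ids Optional character vector of curated exclusions.
#' @param per_population Assess the MAF filter per population (default);
#'   `FALSE` pools haplotypes across populations first.
#' @return A tibble of qualifying (variant, population) pairs:
#'   `variant_id`, `gene`, `population`, `maf`.
#' @export
select_qualifying_plofs <- function(variants, freqs, maf_max = 0.02,
                                    exclude_ids = NULL, per_population = TRUE) {
  stopifnot(all(c("variant_id", "impact_class", "gene", "plof_confidence")
                %in% names(variants)),
            all(c("variant_id", "population", "p_hat") %in% names(freqs)))
  plof <- variants |>
    dplyr::filter(.data$impact_class == "plof",
                  .data$plof_confidence == "high",
                  !.data$variant_id %in% exclude_ids,
                  !is.na(.data$gene))
  if (!per_population) {
    stopifnot("n" %in% names(freqs))
    freqs <- freqs |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(
        pooled = sum(.data$p_hat * 2 * .data$n) / sum(2 * .data$n),
        .groups = "drop"
      ) |>
      dplyr::left_join(dplyr::distinct(freqs, .data$variant_id, .data$population),
                       by = "variant_id") |>
      dplyr::rename(p_hat = "pooled")
  }
  freqs |>
    dplyr::semi_join(plof, by = "variant_id") |>
    dplyr::mutate(maf = pmin(.data$p_hat, 1 - .data$p_hat)) |>
    dplyr::filter(.data$maf < maf_max, .data$maf > 0) |>
    dplyr::left_join(dplyr::select(plof, "variant_id", "gene"),
                     by = "variant_id") |>
    dplyr::select("variant_id", "gene", "population", "maf")
}

#' Per-population allele frequency table for all variants
#'
#' @param panel A [new_cohort_panel()] object.
#' @return Tibble: `variant_id`, `population`, `n`, `p_hat`.
#' @export
panel_frequencies <- function(panel) {
  panel_counts(panel) |>
    dplyr::transmute(
      variant_id = .data$variant_id,
      population = .data$population,
      n = .data$n_called,
      p_hat = ifelse(.data$n_called > 0,
                     .data$alt_haps / (2 * .data$n_called), 0)
    )
}

#' Collapse qualifying pLOFs into gene-level biallelic genotypes (geneLOF)
#'
#' For each individual and gene, counts how many of the two haplotypes carry
#' at least one qualifying pLOF in that gene (0, 1 or 2). Two different
#' pLOFs of the same gene on opposite haplotypes — a compound heterozygote —
#' therefore yield 2 (a knockout), while two pLOFs in cis yield 1. The
#' result is sparse: only individual-gene pairs with at least one affected
#' haplotype are returned; all other pairs are 0. Missing haplotype calls
#' count as unaffected (conservative for deficit detection); the number of
#' missing qualifying sites is reported per pair.
#'
#' @param panel A [new_cohort_panel()] object (phased by construction; the
#'   readers reject unphased genotypes).
#' @param qualifying Output of [select_qualifying_plofs()] (qualification may
#'   differ between populations).
#' @return A tibble of class `lethalscan_genelof`: `population`,
#'   `individual`, `gene`, `haplotypes_affected` (1 or 2), `n_missing_sites`.
#'   Population sizes travel as attribute `"pop_sizes"` so that downstream
#'   scans know the implicit zeros.
#' @export
collapse_to_genelof <- function(panel, qualifying) {
  stopifnot(inherits(panel, "cohort_panel"),
            all(c("variant_id", "gene", "population") %in% names(qualifying)))
  out <- purrr::map_dfr(panel$populations, function(pop) {
    q <- qualifying[qualifying$population == pop$name, , drop = FALSE]
    q <- q[order(q$variant_id), , drop = FALSE]  # order-independence
    if (!nrow(q)) return(NULL)
    genes <- sort(unique(q$gene))
    vidx <- match(q$variant_id, colnames(pop$haps))
    if (anyNA(vidx)) stop("qualifying variant absent from panel", call. = FALSE)
    memb <- Matrix::sparseMatrix(i = vidx, j = match(q$gene, genes), x = 1,
                                 dims = c(ncol(pop$haps), length(genes)),
                                 dimnames = list(NULL, genes))
    a <- .hap_a(pop$haps); b <- .hap_b(pop$haps)
    aff <- ((a %*% memb) > 0) + ((b %*% memb) > 0)
    nz <- Matrix::which(aff > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    miss_cnt <- rep(0, nrow(nz))
    if (!is.null(pop$miss)) {
      mi <- (.hap_a(pop$miss) + .hap_b(pop$miss)) %*% memb
      miss_cnt <- mi[nz]
    }
    ids <- pop$individuals %||% sprintf("%s_%04d", pop$name, seq_len(pop$n))
    tibble::tibble(
      population = pop$name,
      individual = ids[nz[, 1]],
      gene = genes[nz[, 2]],
      haplotypes_affected = as.integer(aff[nz]),
      n_missing_sites = as.numeric(miss_cnt)
    )
  })
  if (is.null(out) || !nrow(out)) {
    out <- tibble::tibble(population = character(), individual = character(),
                          gene = character(), haplotypes_affected = integer(),
                          n_missing_sites = numeric())
  }
  out <- dplyr::arrange(out, .data$population, .data$gene, .data$individual)
  attr(out, "pop_sizes") <- vapply(panel$populations, `[[`, numeric(1), "n")
  class(out) <- c("lethalscan_genelof", class(out))
  out
}

#' Catalogue human gene knockouts
#'
#' A knockout is an individual with both haplotypes affected
#' (`haplotypes_affected == 2`) for a gene, including compound
#' heterozygotes.
#'
#' @param genelof A [collapse_to_genelof()] result.
#' @return A list of class `knockout_catalogue`:
#'   `n_individuals_with_knockout`, `per_individual` (tibble of knockout
#'   gene counts per individual), `genes_knocked_out`,
#'   `genes_with_ge2_knockouts`.
#' @export
build_knockout_catalogue <- function(genelof) {
  ko <- genelof[genelof$haplotypes_affected == 2L, , drop = FALSE]
  per_ind <- ko |>
    dplyr::count(.data$population, .data$individual, name = "n_genes_knocked_out")
  per_gene <- ko |> dplyr::count(.data$gene, name = "n_knockouts")
  structure(list(
    n_individuals_with_knockout = nrow(per_ind),
    per_individual = tibble::as_tibble(per_ind),
    genes_knocked_out = sort(per_gene$gene),
    genes_with_ge2_knockouts = sort(per_gene$gene[per_gene$n_knockouts >= 2])
  ), class = "knockout_catalogue")
}

#' @export
print.knockout_catalogue <- function(x, ...) {
  cat("<knockout_catalogue> ", x$n_individuals_with_knockout,
      " individual(s) with a knockout; ", length(x$genes_knocked_out),
      " gene(s) knocked out (", length(x$genes_with_ge2_knockouts),
      " with >= 2 knockouts)\n", sep = "")
  invisible(x)
}

#' @export
glance.knockout_catalogue <- function(x, ...) {
  tibble::tibble(
    n_individuals_with_knockout = x$n_individuals_with_knockout,
    n_individuals_single_knockout =
      sum(x$per_individual$n_genes_knocked_out == 1),
    n_genes_knocked_out = length(x$genes_knocked_out),
    n_genes_ge2_knockouts = length(x$genes_with_ge2_knockouts)
  )
}

#' Gene-based deficit scan over geneLOF genotypes
#'
#' Treats each gene's geneLOF as a biallelic unit: the carrier haplotype
#' frequency in population `i` is the number of affected haplotypes divided
#' by `2 n_i`, the expected knockout count is `lambda = sum_i n_i p_i^2`,
#' and the observed count is the number of individuals with both haplotypes
#' affected. Classification and the Poisson test are shared with the
#' single-variant scan.
#'
#' @inheritParams classify_strong_deficit
#' @param genelof A [collapse_to_genelof()] result.
#' @param pop_sizes Named numeric vector of population sizes; defaults to the
#'   attribute carried by `genelof`.
#' @return A tibble like [deficit_scan()]'s, with `unit_id` = gene and
#'   `impact_class = "genelof"`.
#' @export
genelof_deficit_scan <- function(genelof, pop_sizes = attr(genelof, "pop_sizes"),
                                 deficit_ratio = 0.1, min_lambda = 0.5) {
  if (is.null(pop_sizes)) stop("population sizes are required", call. = FALSE)
  per <- genelof |>
    dplyr::group_by(.data$gene, .data$population) |>
    dplyr::summarise(
      carrier_haps = sum(.data$haplotypes_affected),
      observed = sum(.data$haplotypes_affected == 2L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = unname(pop_sizes[.data$population]),
      p_hat = .data$carrier_haps / (2 * .data$n)
    )
  out <- per |>
    dplyr::group_by(unit_id = .data$gene) |>
    dplyr::summarise(
      maf = sum(.data$carrier_haps) / sum(2 * .data$n),
      lambda = sum(.data$n * .data$p_hat^2),
      observed = sum(.data$observed),
      .groups = "drop"
    ) |>
    dplyr::mutate(impact_class = "genelof", gene = .data$unit_id)
  cls <- classify_strong_deficit(out$observed, out$lambda,
                                 deficit_ratio = deficit_ratio,
                                 min_lambda = min_lambda)
  out <- dplyr::bind_cols(out, cls)
  out$p_poisson <- ifelse(out$lambda > 0,
                          stats::ppois(out$observed, out$lambda), NA_real_)
  out[, c("unit_id", "impact_class", "gene", "maf", "lambda", "observed",
          "ratio", "tested", "strong_deficit", "p_poisson")]
}
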