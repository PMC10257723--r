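#' Haplotype linkage disequilibrium r-squared
#'
#' Computed on haplotypes pooled across populations:
#' `r2 = (p_AB - p_A p_B)^2 / (p_A q_A p_B q_B)`, defined as 0 when either
#' variant is monomorphic.
#'
#' @param panel A [new_cohort_panel()] object.
#' @param variant_a,variant_b Variant identifiers.
#' @return A scalar in `[0, 1]`.
#' @export
haplotype_r2 <- function(panel, variant_a, variant_b) {
  stopifnot(inherits(panel, "cohort_panel"))
  h <- pooled_haps(panel)
  if (!all(c(variant_a, variant_b) %in% colnames(h))) {
    stop("both variants must be present in the panel", call. = FALSE)
  }
  x <- h[, variant_a]; y <- h[, variant_b]
  n <- length(x)
  pa <- sum(x) / n; pb <- sum(y) / n
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) return(0)
  pab <- sum(x * y) / n
  min(unname((pab - pa * pb)^2 / den), 1)
}

# impact class hierarchy, low to high
impact_levels <- function() c("intergenic", "low", "moderate", "plof")

#' Cross-class linkage-disequilibrium exclusion
#'
#' Removes variants that hitchhike with functionally more severe variants:
#' a variant is dropped from its impact class when its haplotype r-squared
#' with any variant of a strictly higher class (hierarchy
#' intergenic < low < moderate < plof) exceeds the threshold. pLOF variants,
#' being the top class, are never removed.
#'
#' @param panel A [new_cohort_panel()] object whose variant table carries
#'   `impact_class`.
#' @param r2_threshold Exclusion threshold; default 0.8.
#' @return The panel's variant table with columns `retained` (logical) and
#'   `max_r2_higher` (largest r-squared with any higher-class variant)
#'   appended.
#' @export
crossclass_ld_exclude <- function(panel, r2_threshold = 0.8) {
  stopifnot(inherits(panel, "cohort_panel"))
  variants <- panel$variants
  stopifnot("impact_class" %in% names(variants))
  h <- pooled_haps(panel)
  n <- nrow(h)
  p <- Matrix::colSums(h) / n
  lev <- impact_levels()
  rank <- match(variants$impact_class, lev)
  max_r2 <- rep(0, nrow(variants))
  for (k in seq_len(length(lev) - 1)) {
    lo <- which(rank == k)
    hi <- which(rank > k)
    if (!length(lo) || !length(hi)) next
    pab <- as.matrix(Matrix::crossprod(h[, lo, drop = FALSE],
                                       h[, hi, drop = FALSE])) / n
    num <- (pab - outer(p[lo], p[hi]))^2
    den <- outer(p[lo] * (1 - p[lo]), p[hi] * (1 - p[hi]))
    r2 <- pmin(ifelse(den > 0, num / den, 0), 1)  # clamp numerical overshoot
    max_r2[lo] <- apply(r2, 1, max)
  }
  variants |>
    dplyr::mutate(max_r2_higher = max_r2,
                  retained = max_r2 <= r2_threshold)
}

#' Intergenic variant sets by distance from genes
#'
#' Assigns each variant to the nested intergenic distance sets used for FDR
#' calibration: a variant belongs to the distance-`d` set when its position
#' lies more than `d` bases from every genic interval.
#'
#' @param variants Tibble with `variant_id`, `chrom` and 1-based `pos`.
#' @param gene_intervals Tibble of genic intervals in BED convention:
#'   `chrom`, `start` (0-based), `end` (half-open).
#' @param distances Distance thresholds in bases; defaults to
#'   5 kb / 50 kb / 100 kb / 250 kb / 500 kb.
#' @return `variants` with a `dist_to_gene` column (`Inf` when the
#'   chromosome has no genes) and one logical `beyond_<d>` column per
#'   threshold.
#' @export
classify_intergenic_by_distance <- function(variants, gene_intervals,
                                            distances = c(5e3, 5e4, 1e5, 2.5e5, 5e5)) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("chrom", "start", "end") %in% names(gene_intervals)))
  if (any(gene_intervals$end <= gene_intervals$start)) {
    stop("malformed gene intervals: end must exceed start (BED half-open)",
         call. = FALSE)
  }
  genes <- GenomicRanges::GRanges(
    gene_intervals$chrom,
    IRanges::IRanges(start = gene_intervals$start + 1L, end = gene_intervals$end)
  )
  sites <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(start = variants$pos, width = 1L)
  )
  # a chromosome with no genes is legitimate: silence the seqlevels chatter
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(sites, genes, ignore.strand = TRUE))
  # GRanges reports the gap between ranges; the distance from a position to
  # the nearest genic base is gap + 1 for disjoint sites, 0 inside a gene
  gap <- rep(Inf, length(sites))
  gap[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  inside <- suppressWarnings(IRanges::overlapsAny(sites, genes))
  dist <- ifelse(inside, 0, gap + 1)
  out <- dplyr::mutate(variants, dist_to_gene = dist)
  for (d in distances) {
    out[[paste0("beyond_", format(d, scientific = FALSE, trim = TRUE))]] <-
      dist > d
  }
  out
}
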