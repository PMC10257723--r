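#' Cohort panel of phased haplotypes
#'
#' A `cohort_panel` holds phased biallelic haplotype calls for one or more
#' populations over a shared variant set. Internally each population stores a
#' sparse 0/1 matrix with two rows per individual (rows `2i - 1` and `2i` are
#' the two haplotypes of individual `i`) and one column per variant; a `1`
#' marks the alternate allele. Missing haplotype calls, when present, are
#' tracked in a parallel sparse indicator matrix and the individual is treated
#' as ungenotyped for that variant when counting.
#'
#' @param variants A tibble describing the shared variant set. Must contain
#'   `variant_id`; recognised annotation columns are `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `impact_class` (`"intergenic"`, `"low"`, `"moderate"`,
#'   `"plof"`), `gene` and `plof_confidence` (`"high"`, `"low"`,
#'   `"not_applicable"`).
#' @param populations A named list; each element a list with fields `name`,
#'   `n` (number of individuals), `haps` (sparse `2n x n_variants` matrix) and
#'   optionally `miss`, `individuals`, `f`, `ibd`.
#' @param config Optional simulation configuration echo (kept so that
#'   downstream operations such as [apply_recessive_selection()] can use the
#'   generating truth).
#'
#' @return An object of class `cohort_panel`.
#' @seealso [cohort_panel_from_genotypes()], [read_panel()],
#'   [simulate_haplotype_panel()]
#' @export
new_cohort_panel <- function(variants, populations, config = NULL) {
  variants <- tibble::as_tibble(variants)
  stopifnot("variant_id" %in% names(variants))
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant_id in variant table", call. = FALSE)
  }
  for (pop in populations) {
    stopifnot(is.list(pop), !is.null(pop$name), !is.null(pop$n), !is.null(pop$haps))
    if (pop$n < 1) stop("population '", pop$name, "' has no individuals", call. = FALSE)
    if (nrow(pop$haps) != 2L * pop$n) {
      stop("population '", pop$name, "': haplotype matrix must have 2 rows per individual",
           call. = FALSE)
    }
    if (ncol(pop$haps) != nrow(variants)) {
      stop("population '", pop$name, "': haplotype matrix does not match variant table",
           call. = FALSE)
    }
  }
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  structure(list(variants = variants, populations = populations, config = config),
            class = "cohort_panel")
}

#' @export
print.cohort_panel <- function(x, ...) {
  ns <- vapply(x$populations, `[[`, numeric(1), "n")
  cat("<cohort_panel> ", nrow(x$variants), " variants; ",
      length(x$populations), " population(s): ",
      paste0(names(ns), " (n=", format(ns, big.mark = ","), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.cohort_panel <- function(x, ...) {
  tibble::tibble(
    n_populations = length(x$populations),
    n_individuals = sum(vapply(x$populations, `[[`, numeric(1), "n")),
    n_variants = nrow(x$variants)
  )
}

# first / second haplotype rows of a 2n x V matrix
.hap_a <- function(m) m[seq(1L, nrow(m), by = 2L), , drop = FALSE]
.hap_b <- function(m) m[seq(2L, nrow(m), by = 2L), , drop = FALSE]

#' Build a panel from phased genotype strings
#'
#' Convenience constructor used by tests, examples and the VCF reader: takes
#' per-population character matrices of phased genotypes (`"0|1"`, `".|."`)
#' with one row per individual and one column per variant.
#'
#' @param genotypes Named list of character matrices (individuals x variants).
#'   All matrices must share the same column order. Genotypes must use the
#'   phased separator `|`; `/` raises an error.
#' @param variants Optional variant table (see [new_cohort_panel()]). When
#'   omitted, a minimal table is derived from the column names.
#' @return A [new_cohort_panel()] object.
#' @examples
#' gt <- matrix(c("0|1", "0|0", "1|1", "0|0"), ncol = 1,
#'              dimnames = list(NULL, "v1"))
#' cohort_panel_from_genotypes(list(iceland = gt))
#' @export
cohort_panel_from_genotypes <- function(genotypes, variants = NULL) {
  stopifnot(is.list(genotypes), length(genotypes) > 0)
  if (is.null(names(genotypes)) || any(names(genotypes) == "")) {
    stop("genotype matrices must be named by population", call. = FALSE)
  }
  vid <- colnames(genotypes[[1]])
  if (is.null(vid)) vid <- sprintf("v%04d", seq_len(ncol(genotypes[[1]])))
  if (is.null(variants)) {
    variants <- tibble::tibble(
      variant_id = vid, chrom = "1", pos = seq_along(vid) * 1000L,
      ref = "A", alt = "T", impact_class = "intergenic",
      gene = NA_character_, plof_confidence = "not_applicable"
    )
  }
  pops <- lapply(names(genotypes), function(nm) {
    gt <- genotypes[[nm]]
    parsed <- parse_phased_gt(gt, context = nm)
    n <- nrow(gt)
    list(name = nm, n = n,
         individuals = rownames(gt) %||% sprintf("%s_%04d", nm, seq_len(n)),
         haps = parsed$haps, miss = parsed$miss)
  })
  new_cohort_panel(variants, pops)
}

# Parse a matrix of phased genotype strings into sparse haplotype matrices.
# Returns list(haps = 2n x V sparse 0/1, miss = 2n x V sparse indicator or NULL).
parse_phased_gt <- function(gt, context = "panel") {
  n <- nrow(gt); v <- ncol(gt)
  flat <- as.vector(gt)
  flat[is.na(flat) | flat %in% c(".", "./.")] <- ".|."  # missing, not unphased
  if (any(grepl("/", flat, fixed = TRUE))) {
    bad <- which(grepl("/", gt, fixed = TRUE), arr.ind = TRUE)[1, ]
    stop("unphased genotype ('/' separator) in ", context,
         " at individual ", bad[1], ", variant ",
         colnames(gt)[bad[2]] %||% bad[2],
         "; phased GT ('|') is required", call. = FALSE)
  }
  parts <- strsplit(flat, "|", fixed = TRUE)
  len <- lengths(parts)
  if (any(len != 2L)) {
    bad <- which(len != 2L)[1]
    stop("non-diploid genotype '", flat[bad], "' in ", context, call. = FALSE)
  }
  al <- matrix(suppressWarnings(as.integer(unlist(parts))), nrow = 2L)
  a1 <- matrix(al[1, ], nrow = n, ncol = v)
  a2 <- matrix(al[2, ], nrow = n, ncol = v)
  if (any(stats::na.omit(as.vector(al)) > 1L)) {
    stop("multiallelic allele index in ", context,
         "; split records into biallelic units first", call. = FALSE)
  }
  sparse_from_alleles(a1, a2, n, v, colnames(gt))
}

# a1/a2: n x v integer matrices of allele codes (0/1, NA = missing)
sparse_from_alleles <- function(a1, a2, n, v, vid) {
  rows_a <- which(a1 == 1L, arr.ind = TRUE)
  rows_b <- which(a2 == 1L, arr.ind = TRUE)
  i <- c(2L * rows_a[, 1] - 1L, 2L * rows_b[, 1])
  j <- c(rows_a[, 2], rows_b[, 2])
  haps <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(2L * n, v),
                               dimnames = list(NULL, vid))
  miss <- NULL
  if (anyNA(a1) || anyNA(a2)) {
    ma <- which(is.na(a1), arr.ind = TRUE)
    mb <- which(is.na(a2), arr.ind = TRUE)
    miss <- Matrix::sparseMatrix(
      i = c(2L * ma[, 1] - 1L, 2L * mb[, 1]),
      j = c(ma[, 2], mb[, 2]), x = 1,
      dims = c(2L * n, v), dimnames = list(NULL, vid)
    )
  }
  list(haps = haps, miss = miss)
}

#' Per-population allele and homozygote counts
#'
#' The counting core shared by the scan operations. Individuals with a
#' missing haplotype call at a variant are excluded from both the numerator
#' and the denominator for that variant.
#'
#' @param panel A [new_cohort_panel()] object.
#' @return A tibble with one row per variant per population:
#'   `variant_id`, `population`, `n` (cohort size), `n_called` (individuals
#'   genotyped for the variant), `alt_haps` (alternate haplotype count among
#'   called individuals) and `hom` (observed alternate homozygotes).
#' @export
panel_counts <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  purrr::map_dfr(panel$populations, function(pop) {
    a <- .hap_a(pop$haps); b <- .hap_b(pop$haps)
    alt <- Matrix::colSums(a) + Matrix::colSums(b)
    hom <- Matrix::colSums(a * b)
    n_called <- rep(pop$n, ncol(pop$haps))
    if (!is.null(pop$miss)) {
      miss_ind <- ((.hap_a(pop$miss) + .hap_b(pop$miss)) > 0) * 1
      n_called <- pop$n - Matrix::colSums(miss_ind)
      alt <- alt - Matrix::colSums((a + b) * miss_ind)
      hom <- hom - Matrix::colSums((a * b) * miss_ind)
    }
    tibble::tibble(
      variant_id = colnames(pop$haps) %||% panel$variants$variant_id,
      population = pop$name,
      n = pop$n,
      n_called = as.numeric(n_called),
      alt_haps = as.numeric(alt),
      hom = as.numeric(hom)
    )
  })
}

# pooled haplotype matrix across populations (used for LD)
pooled_haps <- function(panel) {
  do.call(rbind, lapply(panel$populations, `[[`, "haps"))
}
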