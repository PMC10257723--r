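#' Read phased VCFs into a cohort panel
#'
#' One VCF per population. Genotypes must be phased (`|` separator;
#' unphased `/` raises an error naming the record) and diploid.
#' Multiallelic records are decomposed into one biallelic unit per alternate
#' allele (id suffixed `_alt<k>`); missing calls are recorded as missing.
#' Variants absent from a population contribute frequency 0 there.
#'
#' @param vcf_paths Named character vector: population name -> VCF path.
#' @param annotation Optional annotation table ([read_annotation()]) merged
#'   onto the variant set by `variant_id`.
#' @return A [new_cohort_panel()] object.
#' @export
read_panel <- function(vcf_paths, annotation = NULL) {
  stopifnot(length(vcf_paths) >= 1, !is.null(names(vcf_paths)),
            all(names(vcf_paths) != ""))
  parsed <- lapply(names(vcf_paths), function(popname) {
    v <- vcfR::read.vcfR(vcf_paths[[popname]], verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- t(fx)  # single-record VCFs drop dimensions
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) {
      gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
    }
    units <- decompose_biallelic(fix, gt, popname)
    units
  })
  names(parsed) <- names(vcf_paths)
  all_vars <- dplyr::bind_rows(lapply(parsed, `[[`, "variants")) |>
    dplyr::distinct(.data$variant_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$variant_id)
  pops <- lapply(names(parsed), function(popname) {
    u <- parsed[[popname]]
    n <- u$n
    idx <- match(all_vars$variant_id, u$variants$variant_id)
    v <- nrow(all_vars)
    a1 <- matrix(0L, n, v); a2 <- matrix(0L, n, v)
    present <- !is.na(idx)
    a1[, present] <- u$a1[, idx[present], drop = FALSE]
    a2[, present] <- u$a2[, idx[present], drop = FALSE]
    sp <- sparse_from_alleles(a1, a2, n, v, all_vars$variant_id)
    list(name = popname, n = n, individuals = u$individuals,
         haps = sp$haps, miss = sp$miss)
  })
  variants <- all_vars
  if (!is.null(annotation)) {
    variants <- variants |>
      dplyr::select(-dplyr::any_of(setdiff(names(annotation), "variant_id"))) |>
      dplyr::left_join(annotation, by = "variant_id")
  }
  new_cohort_panel(variants, pops)
}

# Split (possibly multiallelic) VCF records into biallelic allele matrices.
decompose_biallelic <- function(fix, gt, popname) {
  n <- ncol(gt)
  individuals <- colnames(gt)
  flat <- as.vector(t(gt))  # record-major
  flat[is.na(flat) | flat %in% c(".", "./.")] <- ".|."  # missing, not unphased
  bad <- grepl("/", flat, fixed = TRUE)
  if (any(bad)) {
    k <- which(bad)[1]
    rec <- (k - 1) %/% n + 1
    stop("unphased genotype in population '", popname, "' at record ",
         fix$CHROM[rec], ":", fix$POS[rec], "; phased GT ('|') is required",
         call. = FALSE)
  }
  parts <- strsplit(flat, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("non-diploid genotype in population '", popname, "'", call. = FALSE)
  }
  al <- matrix(suppressWarnings(as.integer(unlist(parts))), nrow = 2L)
  # record x individual allele matrices
  a1 <- matrix(al[1, ], ncol = n, byrow = TRUE)
  a2 <- matrix(al[2, ], ncol = n, byrow = TRUE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  out_vars <- list(); out_a1 <- list(); out_a2 <- list()
  for (r in seq_len(nrow(fix))) {
    base_id <- if (!is.null(fix$ID) && !is.na(fix$ID[r]) && fix$ID[r] != ".") {
      fix$ID[r]
    } else {
      paste0(fix$CHROM[r], "_", fix$POS[r])
    }
    n_alt <- length(alts[[r]])
    for (k in seq_len(n_alt)) {
      vid <- if (n_alt == 1) base_id else paste0(base_id, "_alt", k)
      out_vars[[length(out_vars) + 1]] <- tibble::tibble(
        variant_id = vid, chrom = fix$CHROM[r],
        pos = as.integer(fix$POS[r]), ref = fix$REF[r], alt = alts[[r]][k]
      )
      out_a1[[length(out_a1) + 1]] <- ifelse(is.na(a1[r, ]), NA_integer_,
                                             as.integer(a1[r, ] == k))
      out_a2[[length(out_a2) + 1]] <- ifelse(is.na(a2[r, ]), NA_integer_,
                                             as.integer(a2[r, ] == k))
    }
  }
  list(variants = dplyr::bind_rows(out_vars),
       a1 = t(do.call(rbind, out_a1)),  # individuals x units
       a2 = t(do.call(rbind, out_a2)),
       n = n, individuals = individuals)
}

#' Write a cohort panel as one phased VCF per population
#'
#' @param panel A [new_cohort_panel()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_<population>.vcf`.
#' @return Invisibly, the written paths (named by population).
#' @export
write_panel_vcf <- function(panel, dir, prefix = "panel") {
  stopifnot(inherits(panel, "cohort_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- panel$variants
  paths <- vapply(panel$populations, function(pop) {
    path <- file.path(dir, paste0(prefix, "_", pop$name, ".vcf"))
    a <- as.matrix(.hap_a(pop$haps)); b <- as.matrix(.hap_b(pop$haps))
    gt <- matrix(paste0(a, "|", b), nrow = pop$n)
    if (!is.null(pop$miss)) {
      ma <- as.matrix(.hap_a(pop$miss)) > 0; mb <- as.matrix(.hap_b(pop$miss)) > 0
      gt[ma | mb] <- ".|."
    }
    ids <- pop$individuals %||% sprintf("%s_%04d", pop$name, seq_len(pop$n))
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", ids), collapse = "\t"))
    body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                  ".", "GT", t(gt))
    lines <- c(header, apply(body, 1, paste, collapse = "\t"))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

annotation_cols <- function() {
  c("variant_id", "chrom", "pos", "impact_class", "gene", "plof_confidence")
}

#' Read / write a variant annotation table
#'
#' Tab-separated with columns `variant_id`, `chrom`, `pos`, `impact_class`,
#' `gene`, `plof_confidence` (simulator truth columns such as
#' `survival_fraction` and `freq_<population>` round-trip unchanged).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           gene = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  missing <- setdiff(c("variant_id", "impact_class"), names(out))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(out$impact_class), impact_levels())
  if (length(bad)) {
    stop("unknown impact_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_annotation
#' @param variants Variant table to write.
#' @export
write_annotation <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read a gene-set membership table
#'
#' Tab-separated, two columns: `gene`, `set`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_gene_sets <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("gene", "set") %in% names(out)))
  out
}

#' Read a couples table
#'
#' Tab-separated with at least `couple_id`, `mother`, `father`; outcome and
#' covariate columns (`n_pregnancies`, `n_miscarriages`, `ever_miscarriage`,
#' `birth_year`, ...) are carried through.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_couples <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("couple_id", "mother", "father") %in% names(out)))
  if (!"ever_miscarriage" %in% names(out) && "n_miscarriages" %in% names(out)) {
    out$ever_miscarriage <- out$n_miscarriages >= 1
  }
  out
}

#' Read a BED region mask
#'
#' Three columns (no header): chromosome, 0-based start, half-open end.
#'
#' @param path File path.
#' @return A tibble: `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  out <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", comment = "#")
  if (any(out$end <= out$start)) {
    stop("malformed BED intervals: end must exceed start", call. = FALSE)
  }
  out
}

#' Restrict variants to a high-confidence region mask
#'
#' Variants whose 1-based position falls outside every mask interval are
#' dropped (the mask is consumed, not built: supply e.g. Tier 1
#' high-confidence regions).
#'
#' @param variants Variant table with `chrom` and `pos`.
#' @param mask A [read_bed_mask()] tibble (BED convention).
#' @return The masked variant table.
#' @export
apply_region_mask <- function(variants, mask) {
  sites <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(start = variants$pos, width = 1L))
  keep <- GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  hits <- GenomicRanges::findOverlaps(sites, keep)
  variants[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
}
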