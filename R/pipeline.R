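#' Pipeline configuration
#'
#' Thresholds default to the scan's canonical values: strong-deficit ratio
#' 0.1, minimum tested expected count 0.5, geneLOF MAF bound 2%, LD
#' exclusion r-squared 0.8, alpha 0.05 and the standard expected-count bin
#' edges. Every threshold is overridable and the full configuration is
#' echoed verbatim (with a hash) into the output metadata.
#'
#' @param vcf_paths Named character vector population -> phased VCF path
#'   (omit when a panel object is passed to [run_pipeline()] directly).
#' @param annotation_path,mask_path,gene_sets_path,couples_path,exclusion_path
#'   Optional input files: annotation TSV, BED region mask, gene-set TSV,
#'   couples TSV, curated pLOF exclusion id list (one id per line).
#' @param deficit_ratio,min_lambda,genelof_maf,r2_threshold,alpha,bin_edges
#'   Scan thresholds.
#' @param intergenic_distance Distance (bases) defining the intergenic
#'   calibration set; default 5 kb.
#' @param match_ratio Controls per carrier couple; default 100.
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf_paths = NULL, annotation_path = NULL,
                            mask_path = NULL, gene_sets_path = NULL,
                            couples_path = NULL, exclusion_path = NULL,
                            deficit_ratio = 0.1, min_lambda = 0.5,
                            genelof_maf = 0.02, r2_threshold = 0.8,
                            alpha = 0.05, bin_edges = fdr_bin_edges(),
                            intergenic_distance = 5e3, match_ratio = 100,
                            seed = 1L, out_dir = NULL) {
  structure(list(
    vcf_paths = vcf_paths, annotation_path = annotation_path,
    mask_path = mask_path, gene_sets_path = gene_sets_path,
    couples_path = couples_path, exclusion_path = exclusion_path,
    deficit_ratio = deficit_ratio, min_lambda = min_lambda,
    genelof_maf = genelof_maf, r2_threshold = r2_threshold, alpha = alpha,
    bin_edges = bin_edges, intergenic_distance = intergenic_distance,
    match_ratio = match_ratio, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$vcf_paths)) vals$vcf_paths <- unlist(vals$vcf_paths)
  do.call(pipeline_config, vals)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full deficit-of-homozygosity pipeline
#'
#' Orchestrates: region-mask filtering, cross-class LD exclusion, the
#' single-variant deficit scan, the gene-based geneLOF scan, FDR calibration
#' against intergenic variants, gene-set over-representation and — when a
#' couples table is supplied — the carrier-couple miscarriage analysis.
#' Per-stage unit counts (the analysis funnel) are logged and returned;
#' every output file carries the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param panel Optional pre-built [new_cohort_panel()]; otherwise read from
#'   `config$vcf_paths`.
#' @param gene_sets,couples Optional in-memory tables overriding the
#'   configured paths.
#' @param quiet Suppress progress messages.
#' @return A list of class `lethalscan_run` with elements `scan`,
#'   `genelof`, `genelof_scan`, `knockouts`, `fdr`, `enrichment`, `couples`,
#'   `funnel`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config, panel = NULL, gene_sets = NULL,
                         couples = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[lethalscan] ", ...)
  funnel <- list()
  note <- function(stage, n) {
    funnel[[stage]] <<- n
    say(stage, ": ", n)
  }

  panel <- pipeline_stage("read_panel", {
    if (is.null(panel)) {
      if (is.null(config$vcf_paths)) {
        stop("no panel and no vcf_paths configured")
      }
      ann <- if (!is.null(config$annotation_path)) {
        read_annotation(config$annotation_path)
      }
      read_panel(config$vcf_paths, annotation = ann)
    } else {
      panel
    }
  })
  note("variants_input", nrow(panel$variants))

  if (!is.null(config$mask_path)) {
    panel <- pipeline_stage("region_mask", {
      mask <- read_bed_mask(config$mask_path)
      kept <- apply_region_mask(panel$variants, mask)
      subset_panel(panel, kept$variant_id)
    })
    note("variants_after_mask", nrow(panel$variants))
  }

  ld <- pipeline_stage("ld_exclusion",
                       crossclass_ld_exclude(panel, config$r2_threshold))
  panel_scan <- subset_panel(panel, ld$variant_id[ld$retained])
  note("variants_after_ld", nrow(panel_scan$variants))

  scan <- pipeline_stage("deficit_scan",
                         deficit_scan(panel_scan,
                                      deficit_ratio = config$deficit_ratio,
                                      min_lambda = config$min_lambda))
  note("variants_tested", sum(scan$tested))
  note("variants_strong_deficit", sum(scan$strong_deficit))

  exclusion <- if (!is.null(config$exclusion_path)) {
    readLines(config$exclusion_path)
  }
  qualifying <- pipeline_stage("select_plofs",
                               select_qualifying_plofs(
                                 panel$variants, panel_frequencies(panel),
                                 maf_max = config$genelof_maf,
                                 exclude_ids = exclusion))
  genelof <- pipeline_stage("collapse_genelof",
                            collapse_to_genelof(panel, qualifying))
  knockouts <- build_knockout_catalogue(genelof)
  gscan <- pipeline_stage("genelof_scan",
                          genelof_deficit_scan(genelof,
                                               deficit_ratio = config$deficit_ratio,
                                               min_lambda = config$min_lambda))
  note("genes_tested", sum(gscan$tested))
  note("genes_strong_deficit", sum(gscan$strong_deficit))

  fdr <- pipeline_stage("fdr_calibration", {
    if ("intergenic" %in% scan$impact_class[scan$tested]) {
      fdr_calibrate(scan, edges = config$bin_edges)
    } else {
      NULL
    }
  })

  if (is.null(gene_sets) && !is.null(config$gene_sets_path)) {
    gene_sets <- read_gene_sets(config$gene_sets_path)
  }
  enrichment <- if (!is.null(gene_sets)) {
    pipeline_stage("enrichment",
                   overrepresentation_by_bin(gscan, gene_sets))
  }

  if (is.null(couples) && !is.null(config$couples_path)) {
    couples <- read_couples(config$couples_path)
  }
  couples_res <- if (!is.null(couples)) {
    pipeline_stage("couples", {
      deficit_genes <- gscan$unit_id[gscan$strong_deficit]
      if (length(deficit_genes)) {
        individuals <- unlist(lapply(panel$populations, `[[`, "individuals"))
        status <- identify_carrier_couples(genelof, couples, individuals,
                                           genes = deficit_genes)
        run_couples_tests(status, config)
      }
    })
  }

  config_hash <- rlang::hash(config)
  out <- structure(list(scan = scan, genelof = genelof, genelof_scan = gscan,
                        knockouts = knockouts, fdr = fdr,
                        enrichment = enrichment, couples = couples_res,
                        funnel = tibble::tibble(stage = names(funnel),
                                                n = unname(unlist(funnel))),
                        config = config, config_hash = config_hash),
                   class = "lethalscan_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

# carrier-couple tests per deficit gene plus the combined test
run_couples_tests <- function(status, config) {
  genes <- unique(status$gene)
  pool <- status |>
    dplyr::group_by(.data$couple_id) |>
    dplyr::filter(all(.data$carrier_status == "neither")) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  cases_all <- status |>
    dplyr::filter(.data$carrier_status == "both") |>
    dplyr::distinct(.data$couple_id, .keep_all = TRUE)
  per_gene <- purrr::map_dfr(genes, function(g) {
    cases <- status[status$gene == g & status$carrier_status == "both", ,
                    drop = FALSE]
    if (!nrow(cases)) return(NULL)
    controls <- match_control_couples(cases, pool, ratio = config$match_ratio,
                                      seed = config$seed)
    ft <- miscarriage_ever_test(cases, controls)
    dplyr::mutate(tidy(ft), gene = g, n_couples = nrow(cases),
                  n_miscarriage_ever = sum(cases$ever_miscarriage),
                  .before = 1)
  })
  combined <- NULL
  if (nrow(cases_all)) {
    controls <- match_control_couples(cases_all, pool,
                                      ratio = config$match_ratio,
                                      seed = config$seed)
    combined <- list(
      ever = miscarriage_ever_test(cases_all, controls),
      per_pregnancy = miscarriage_per_pregnancy_test(cases_all, controls)
    )
  }
  list(per_gene = per_gene, combined = combined,
       alpha_per_gene = if (length(genes)) {
         bonferroni_threshold(length(genes), config$alpha)
       })
}

# restrict a panel to a subset of variants (order preserved)
subset_panel <- function(panel, variant_ids) {
  keep <- panel$variants$variant_id %in% variant_ids
  idx <- which(keep)
  pops <- lapply(panel$populations, function(pop) {
    pop$haps <- pop$haps[, idx, drop = FALSE]
    if (!is.null(pop$miss)) pop$miss <- pop$miss[, idx, drop = FALSE]
    pop
  })
  new_cohort_panel(panel$variants[idx, , drop = FALSE], pops,
                   config = panel$config)
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- function(tbl) {
    dplyr::mutate(tbl, config_hash = run$config_hash, seed = run$config$seed)
  }
  readr::write_tsv(stamp(run$scan), file.path(dir, "deficit_scan.tsv"))
  readr::write_tsv(stamp(tibble::as_tibble(run$genelof)),
                   file.path(dir, "genelof_matrix.tsv"))
  readr::write_tsv(stamp(run$genelof_scan), file.path(dir, "genelof_scan.tsv"))
  if (!is.null(run$fdr)) {
    readr::write_tsv(stamp(tibble::as_tibble(run$fdr)),
                     file.path(dir, "fdr_calibration.tsv"))
  }
  if (!is.null(run$enrichment)) {
    readr::write_tsv(stamp(run$enrichment), file.path(dir, "enrichment.tsv"))
  }
  jsonlite::write_json(
    c(glance(run$knockouts),
      list(config_hash = run$config_hash, seed = run$config$seed)),
    file.path(dir, "knockout_catalogue.json"), auto_unbox = TRUE)
  readr::write_tsv(stamp(run$funnel), file.path(dir, "funnel.tsv"))
  cfg <- run$config
  cfg$bin_edges <- as.numeric(cfg$bin_edges)  # yaml-safe (Inf -> .inf)
  yaml::write_yaml(c(unclass(cfg), list(config_hash = run$config_hash)),
                   file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' @export
print.lethalscan_run <- function(x, ...) {
  cat("<lethalscan_run> config", substr(x$config_hash, 1, 8), "seed",
      x$config$seed, "\n")
  print(x$funnel)
  invisible(x)
}

#' @export
glance.lethalscan_run <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}

#' Observed/expected homozygote scatter for a deficit scan
#'
#' @param results A [deficit_scan()] or [genelof_deficit_scan()] tibble.
#' @return A ggplot of observed/expected ratio against the expected count
#'   (log scale), with the strong-deficit region shaded.
#' @export
plot_deficit_scan <- function(results) {
  dat <- dplyr::filter(results, .data$tested)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lambda, y = .data$ratio,
                                    colour = .data$strong_deficit)) +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected homozygotes (lambda)",
                  y = "observed / expected",
                  colour = "strong deficit") +
    ggplot2::theme_minimal()
}
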