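#' Population specification for the cohort simulator
#'
#' @param name Population label.
#' @param n_individuals Cohort size (>= 1).
#' @param inbreeding_mean Mean genomic inbreeding coefficient `f` in `[0, 1]`.
#'   Each individual is whole-genome identical-by-descent (second haplotype a
#'   copy of the first) with probability `f_i`, which reproduces the marginal
#'   homozygote inflation `P(hom) = p^2 + f p (1 - p)` exactly while keeping
#'   a phased representation.
#' @param inbreeding_dispersion Spread of `f_i` across individuals; 0 (the
#'   default) makes `f_i` constant, otherwise `f_i ~ Beta` with the given
#'   mean and shape sum `1 / dispersion`. The distribution of inbreeding
#'   across individuals is a modelling choice, not an estimate, and is
#'   therefore exposed as configuration.
#' @return A one-row tibble.
#' @export
population_spec <- function(name, n_individuals, inbreeding_mean = 0,
                            inbreeding_dispersion = 0) {
  stopifnot(n_individuals >= 1, inbreeding_mean >= 0, inbreeding_mean <= 1,
            inbreeding_dispersion >= 0)
  tibble::tibble(name = name, n_individuals = as.integer(n_individuals),
                 inbreeding_mean = inbreeding_mean,
                 inbreeding_dispersion = inbreeding_dispersion)
}

#' Build a block of variant specifications
#'
#' Convenience builder for simulator variant tables: one row per variant
#' with per-population allele frequency columns `freq_<population>`.
#'
#' @param n Number of variants in the block.
#' @param impact_class One of `"intergenic"`, `"low"`, `"moderate"`,
#'   `"plof"`.
#' @param freq Either a single vector of length `n` (same frequency in every
#'   population) or a named list of per-population frequency vectors.
#'   Frequencies must lie in `[0, 0.5]`.
#' @param populations Population names (required when `freq` is unnamed).
#' @param gene Gene labels (recycled); `NA` for intergenic variants.
#' @param plof_confidence pLOF confidence flag (recycled); defaults to
#'   `"high"` for pLOFs and `"not_applicable"` otherwise.
#' @param survival_fraction Survival probability `s` of homozygotes
#'   (recycled); 1 = neutral, 0 = fully recessive-lethal.
#' @param prefix Variant id prefix.
#' @return A tibble block that can be row-bound with other blocks and passed
#'   to [sim_config()].
#' @export
sim_variants <- function(n, impact_class, freq, populations = NULL,
                         gene = NA_character_, plof_confidence = NULL,
                         survival_fraction = 1, prefix = impact_class) {
  stopifnot(impact_class %in% impact_levels())
  if (!is.list(freq)) {
    stopifnot(!is.null(populations))
    freq <- stats::setNames(rep(list(freq), length(populations)), populations)
  }
  if (is.null(plof_confidence)) {
    plof_confidence <- if (impact_class == "plof") "high" else "not_applicable"
  }
  out <- tibble::tibble(
    variant_id = sprintf("%s_%05d", prefix, seq_len(n)),
    impact_class = impact_class,
    gene = rep_len(gene, n),
    plof_confidence = rep_len(plof_confidence, n),
    survival_fraction = rep_len(survival_fraction, n)
  )
  for (pop in names(freq)) {
    out[[paste0("freq_", pop)]] <- rep_len(freq[[pop]], n)
  }
  out
}

#' Couple-history configuration
#'
#' @param n_couples Number of couples to form.
#' @param pregnancies A distribution spec for per-couple pregnancy counts:
#'   `list(dist = "poisson" | "shifted_poisson", mean = <num>)`.
#'   `"shifted_poisson"` draws `1 + Poisson(mean - 1)` so every couple has at
#'   least one pregnancy. Default: shifted Poisson with mean 2.9.
#' @param background_miscarriage_rate Per-pregnancy miscarriage probability
#'   `m0` absent any lethal genotype.
#' @param lethal_miscarriage_prob Probability `pi` that a homozygous
#'   conception for a lethal gene ends in miscarriage. A double-carrier
#'   couple's per-pregnancy miscarriage probability is
#'   `m0 + (1 - m0) * (1/4) * pi`.
#' @param child_death_rate Background probability that a live-born child
#'   dies before age two.
#' @param birth_year_mean,birth_year_sd Mother birth-year distribution used
#'   as a matching covariate.
#' @return A list of class `couple_history_config`.
#' @export
couple_history_config <- function(n_couples,
                                  pregnancies = list(dist = "shifted_poisson",
                                                     mean = 2.9),
                                  background_miscarriage_rate = 0.1,
                                  lethal_miscarriage_prob = 1,
                                  child_death_rate = 0.03,
                                  birth_year_mean = 1950,
                                  birth_year_sd = 10) {
  stopifnot(n_couples >= 1,
            background_miscarriage_rate >= 0, background_miscarriage_rate <= 1,
            lethal_miscarriage_prob >= 0, lethal_miscarriage_prob <= 1,
            child_death_rate >= 0, child_death_rate <= 1,
            pregnancies$dist %in% c("poisson", "shifted_poisson"))
  structure(list(n_couples = as.integer(n_couples), pregnancies = pregnancies,
                 background_miscarriage_rate = background_miscarriage_rate,
                 lethal_miscarriage_prob = lethal_miscarriage_prob,
                 child_death_rate = child_death_rate,
                 birth_year_mean = birth_year_mean,
                 birth_year_sd = birth_year_sd),
            class = "couple_history_config")
}

#' Simulation configuration
#'
#' Bundles populations, variant specifications, gene structure and an
#' optional couple-history block into a validated, fully seeded
#' configuration: the seed determines every downstream draw.
#'
#' @param populations Row-bound [population_spec()] tibble.
#' @param variants Variant table (see [sim_variants()]): `variant_id`,
#'   `impact_class`, `gene`, `plof_confidence`, `survival_fraction` and one
#'   `freq_<population>` column per population (frequencies in `[0, 0.5]`;
#'   0 where a variant is absent from a population).
#' @param gene_count Number of genes available to [assign_gene_structure()].
#' @param seed Integer seed.
#' @param couples Optional [couple_history_config()].
#' @param allow_lethal_any Permit `survival_fraction < 1` outside
#'   moderate/pLOF classes (off by default; lethal intergenic variants are a
#'   deliberate test scenario, not a default).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(populations, variants, gene_count = 1L, seed = 1L,
                       couples = NULL, allow_lethal_any = FALSE) {
  stopifnot(nrow(populations) >= 1, all(populations$n_individuals >= 1),
            all(populations$inbreeding_mean >= 0),
            all(populations$inbreeding_mean <= 1),
            gene_count >= 1)
  req <- c("variant_id", "impact_class", "gene", "plof_confidence",
           "survival_fraction")
  stopifnot(all(req %in% names(variants)))
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant_id", call. = FALSE)
  }
  fcols <- paste0("freq_", populations$name)
  if (!all(fcols %in% names(variants))) {
    stop("variants must carry a freq_<population> column for every population",
         call. = FALSE)
  }
  freqs <- as.matrix(variants[fcols])
  if (any(freqs < 0 | freqs > 0.5)) {
    stop("allele frequencies must lie in [0, 0.5]", call. = FALSE)
  }
  stopifnot(all(variants$survival_fraction >= 0),
            all(variants$survival_fraction <= 1))
  if (!allow_lethal_any &&
      any(variants$survival_fraction < 1 &
          !variants$impact_class %in% c("moderate", "plof"))) {
    stop("survival_fraction < 1 is only allowed for moderate/plof variants ",
         "(set allow_lethal_any = TRUE for test scenarios)", call. = FALSE)
  }
  if (any(variants$impact_class == "intergenic" & !is.na(variants$gene))) {
    stop("intergenic variants must have no gene", call. = FALSE)
  }
  structure(list(populations = populations,
                 variants = tibble::as_tibble(variants),
                 gene_count = as.integer(gene_count), seed = as.integer(seed),
                 couples = couples),
            class = "sim_config")
}

draw_inbreeding <- function(n, mean, dispersion) {
  if (mean <= 0) return(rep(0, n))
  if (dispersion <= 0) return(rep(mean, n))
  k <- 1 / dispersion
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Simulate a multi-population phased haplotype panel
#'
#' Haplotype alleles at each variant are independent Bernoulli(p) draws with
#' the configured per-population frequency; with probability `f_i` an
#' individual's second haplotype is a genome-wide copy of the first,
#' producing the inbreeding-inflated marginal
#' `P(hom-alt) = p^2 + f_i p (1 - p)`. Variants are simulated in linkage
#' equilibrium. Output is byte-identical for identical configuration and
#' seed.
#'
#' @param config A [sim_config()].
#' @return A [new_cohort_panel()] with per-population truth (`f`, `ibd`) and
#'   the configuration attached for downstream operations.
#' @export
simulate_haplotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  variants <- config$variants
  nv <- nrow(variants)
  meta <- variants
  if (!"chrom" %in% names(meta)) meta$chrom <- "1"
  if (!"pos" %in% names(meta)) meta$pos <- seq_len(nv) * 1000L
  if (!"ref" %in% names(meta)) meta$ref <- "A"
  if (!"alt" %in% names(meta)) meta$alt <- "T"
  pops <- lapply(seq_len(nrow(config$populations)), function(k) {
    spec <- config$populations[k, ]
    n <- spec$n_individuals
    f <- draw_inbreeding(n, spec$inbreeding_mean, spec$inbreeding_dispersion)
    ibd <- stats::runif(n) < f
    non_ibd <- which(!ibd)
    p <- variants[[paste0("freq_", spec$name)]]
    trip <- vector("list", nv)
    for (j in seq_len(nv)) {
      if (p[j] == 0) next
      ka <- stats::rbinom(1, n, p[j])
      ia <- if (ka > 0) sample.int(n, ka) else integer()
      kb <- stats::rbinom(1, length(non_ibd), p[j])
      ib <- if (kb > 0) non_ibd[sample.int(length(non_ibd), kb)] else integer()
      ib_copy <- ia[ibd[ia]]          # IBD individuals copy haplotype A
      rows <- c(2L * ia - 1L, 2L * ib, 2L * ib_copy)
      if (length(rows)) trip[[j]] <- cbind(rows, j)
    }
    trip <- do.call(rbind, trip)
    haps <- Matrix::sparseMatrix(
      i = if (is.null(trip)) integer() else trip[, 1],
      j = if (is.null(trip)) integer() else trip[, 2],
      x = 1, dims = c(2L * n, nv),
      dimnames = list(NULL, variants$variant_id)
    )
    list(name = spec$name, n = n,
         individuals = sprintf("%s_%06d", spec$name, seq_len(n)),
         haps = haps, miss = NULL, f = f, ibd = ibd)
  })
  new_cohort_panel(meta, pops, config = config)
}

#' Apply recessive selection against homozygotes
#'
#' Each individual homozygous for a variant with survival fraction `s < 1`
#' is retained with probability `s`; otherwise they are replaced by a
#' freshly drawn non-homozygous individual. The replacement redraws the
#' genotype at the selected variant conditional on it not being homozygous
#' (respecting the individual's identity-by-descent state), which under the
#' simulator's linkage-equilibrium model is distributionally equivalent to
#' redrawing a whole individual while leaving other variants untouched.
#' Population sizes are unchanged and carrier haplotype frequencies are
#' approximately preserved (the perturbation is second order for rare
#' variants).
#'
#' @param panel A panel produced by [simulate_haplotype_panel()].
#' @param seed Integer seed for the selection draws.
#' @return The panel with post-selection haplotypes.
#' @export
apply_recessive_selection <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "cohort_panel"))
  config <- panel$config
  if (is.null(config)) {
    stop("selection requires a simulated panel (generating truth attached)",
         call. = FALSE)
  }
  set.seed(seed)
  sel <- which(panel$variants$survival_fraction < 1)
  if (!length(sel)) return(panel)
  for (pn in names(panel$populations)) {
    pop <- panel$populations[[pn]]
    h <- pop$haps
    pvec <- panel$variants[[paste0("freq_", pn)]]
    zero_i <- zero_j <- integer()  # batched edits: one sparse update per pop
    for (j in sel) {
      s <- panel$variants$survival_fraction[j]
      p <- pvec[j]
      col <- h[, j]
      hom <- which(col[seq(1, length(col), 2)] == 1 &
                     col[seq(2, length(col), 2)] == 1)
      if (!length(hom)) next
      removed <- hom[stats::runif(length(hom)) >= s]
      for (i in removed) {
        ra <- 2L * i - 1L; rb <- 2L * i
        if (pop$ibd[i]) {
          # IBD replacement: conditional on not homozygous, the shared
          # haplotype is reference
          zero_i <- c(zero_i, ra, rb); zero_j <- c(zero_j, j, j)
        } else {
          p_het <- 2 * p * (1 - p) / (1 - p^2)
          if (stats::runif(1) < p_het) {
            drop_row <- if (stats::runif(1) < 0.5) rb else ra
            zero_i <- c(zero_i, drop_row); zero_j <- c(zero_j, j)
          } else {
            zero_i <- c(zero_i, ra, rb); zero_j <- c(zero_j, j, j)
          }
        }
      }
    }
    if (length(zero_i)) {
      h[cbind(zero_i, zero_j)] <- 0
      panel$populations[[pn]]$haps <- Matrix::drop0(h)
    }
  }
  panel
}

#' Assign simulated variants to genes
#'
#' Every non-intergenic variant maps to exactly one of the configuration's
#' `gene_count` genes; intergenic variants map to none. Variant rows that
#' already carry a gene keep it; the rest are assigned uniformly at random,
#' deterministically given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A tibble: `variant_id`, `gene` (`NA` for intergenic).
#' @export
assign_gene_structure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- sprintf("G%04d", seq_len(config$gene_count))
  v <- config$variants
  gene <- v$gene
  needs <- is.na(gene) & v$impact_class != "intergenic"
  gene[needs] <- sample(genes, sum(needs), replace = TRUE)
  gene[v$impact_class == "intergenic"] <- NA_character_
  known <- stats::na.omit(unique(gene))
  extra <- setdiff(known, genes)
  if (length(extra)) {
    stop("variant table references gene(s) outside the configured gene set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(variant_id = v$variant_id, gene = gene)
}

draw_pregnancies <- function(n, spec) {
  switch(spec$dist,
         poisson = stats::rpois(n, spec$mean),
         shifted_poisson = 1L + stats::rpois(n, max(spec$mean - 1, 0)),
         stop("unknown pregnancies distribution: ", spec$dist, call. = FALSE))
}

#' Simulate couple reproductive histories
#'
#' Couples are formed from distinct individuals of one population. For a
#' double-carrier couple — both partners heterozygous geneLOF carriers of a
#' lethal gene — each conception is homozygous with probability 1/4, so the
#' per-pregnancy miscarriage probability is
#' `m0 + (1 - m0) * (1/4) * pi`; all other couples miscarry at the
#' background rate `m0`. Live-born children die before age two at a
#' background rate.
#'
#' @param panel A simulated [new_cohort_panel()].
#' @param gene_map Variant-to-gene map ([assign_gene_structure()] output).
#' @param cfg A [couple_history_config()].
#' @param lethal_genes Genes whose homozygotes are lethal in utero.
#' @param seed Integer seed.
#' @param population Population to draw couples from; default the first.
#' @return A tibble with one row per couple: `couple_id`, `mother`,
#'   `father`, `population`, `truth_double_carrier`, `birth_year`,
#'   `n_pregnancies`, `n_miscarriages`, `n_live_births`, `ever_miscarriage`,
#'   `n_children_dead_before_2`.
#' @export
simulate_couple_histories <- function(panel, gene_map, cfg, lethal_genes,
                                      seed = 1L, population = NULL) {
  stopifnot(inherits(panel, "cohort_panel"),
            inherits(cfg, "couple_history_config"))
  population <- population %||% names(panel$populations)[1]
  pop <- panel$populations[[population]]
  if (is.null(pop)) stop("unknown population: ", population, call. = FALSE)
  n <- pop$n
  if (2L * cfg$n_couples > n) {
    stop("population too small for ", cfg$n_couples, " distinct couples",
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(n, 2L * cfg$n_couples)
  mothers <- idx[seq_len(cfg$n_couples)]
  fathers <- idx[cfg$n_couples + seq_len(cfg$n_couples)]

  # heterozygous-carrier state per individual for the lethal genes
  lethal_variants <- gene_map$variant_id[gene_map$gene %in% lethal_genes &
                                           !is.na(gene_map$gene)]
  lethal_variants <- intersect(lethal_variants, colnames(pop$haps))
  if (length(lethal_variants) && length(lethal_genes)) {
    gm <- gene_map[gene_map$variant_id %in% lethal_variants, ]
    genes <- unique(gm$gene)
    memb <- Matrix::sparseMatrix(
      i = match(gm$variant_id, colnames(pop$haps)),
      j = match(gm$gene, genes), x = 1,
      dims = c(ncol(pop$haps), length(genes))
    )
    a_aff <- (.hap_a(pop$haps) %*% memb) > 0
    b_aff <- (.hap_b(pop$haps) %*% memb) > 0
    het_per_gene <- as.matrix(a_aff + b_aff == 1)  # n x lethal genes, small
    double <- rowSums(het_per_gene[mothers, , drop = FALSE] &
                        het_per_gene[fathers, , drop = FALSE]) > 0
  } else {
    double <- rep(FALSE, cfg$n_couples)
  }

  npreg <- draw_pregnancies(cfg$n_couples, cfg$pregnancies)
  m0 <- cfg$background_miscarriage_rate
  p_mis <- ifelse(double,
                  m0 + (1 - m0) * 0.25 * cfg$lethal_miscarriage_prob,
                  m0)
  nmis <- stats::rbinom(cfg$n_couples, npreg, p_mis)
  nlive <- npreg - nmis
  ndead <- stats::rbinom(cfg$n_couples, nlive, cfg$child_death_rate)
  ids <- pop$individuals %||% sprintf("%s_%06d", population, seq_len(n))
  tibble::tibble(
    couple_id = sprintf("couple_%05d", seq_len(cfg$n_couples)),
    mother = ids[mothers],
    father = ids[fathers],
    population = population,
    truth_double_carrier = double,
    birth_year = round(stats::rnorm(cfg$n_couples, cfg$birth_year_mean,
                                    cfg$birth_year_sd)),
    n_pregnancies = as.integer(npreg),
    n_miscarriages = as.integer(nmis),
    n_live_births = as.integer(nlive),
    ever_miscarriage = nmis >= 1L,
    n_children_dead_before_2 = as.integer(ndead)
  )
}
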