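plof_variants <- function(ids, genes, conf = "high") {
  tibble::tibble(variant_id = ids, impact_class = "plof", gene = genes,
                 plof_confidence = conf)
}

test_that("qualifying pLOFs respect confidence, MAF and curated exclusions", {
  vars <- rbind(
    plof_variants(c("ok", "common", "lowconf", "curated"), "G1",
                  conf = c("high", "high", "low", "high")),
    tibble::tibble(variant_id = "benign", impact_class = "intergenic",
                   gene = NA, plof_confidence = "not_applicable")
  )
  freqs <- tibble::tibble(
    variant_id = c("ok", "common", "lowconf", "curated", "benign"),
    population = "p", p_hat = c(0.01, 0.03, 0.01, 0.01, 0.01), n = 100
  )
  q <- select_qualifying_plofs(vars, freqs, exclude_ids = "curated")
  expect_equal(q$variant_id, "ok")   # 1% high-confidence pLOF only
  # a variant can qualify in one population but not another
  freqs2 <- tibble::tibble(variant_id = "ok", population = c("a", "b"),
                           p_hat = c(0.01, 0.05), n = 100)
  q2 <- select_qualifying_plofs(plof_variants("ok", "G1"), freqs2)
  expect_equal(q2$population, "a")
})

test_that("collapsing counts affected haplotypes, not variants", {
  gt <- cbind(
    v1 = c("1|0", "1|0", "0|0", "1|1"),
    v2 = c("0|1", "1|0", "0|0", "0|0")
  )
  p <- cohort_panel_from_genotypes(
    list(pop = gt),
    variants = tibble::tibble(
      variant_id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
      ref = "A", alt = "T", impact_class = "plof", gene = "G1",
      plof_confidence = "high"
    )
  )
  q <- tibble::tibble(variant_id = c("v1", "v2"), gene = "G1",
                      population = "pop", maf = 0.01)
  gl <- collapse_to_genelof(p, q)
  aff <- setNames(gl$haplotypes_affected, gl$individual)
  expect_equal(unname(aff[gl$individual == "pop_0001"]), 2L)  # trans: knockout
  expect_equal(unname(aff[gl$individual == "pop_0002"]), 1L)  # cis: one haplotype
  expect_false("pop_0003" %in% gl$individual)                 # no qualifying pLOF
  expect_equal(unname(aff[gl$individual == "pop_0004"]), 2L)  # true homozygote
  # order independence / idempotence
  gl_rev <- collapse_to_genelof(p, q[2:1, ])
  expect_equal(as.data.frame(gl), as.data.frame(gl_rev))
})

test_that("geneLOF carrier frequency is bounded by its variants' frequencies", {
  set.seed(23)
  p <- quick_panel(5000, rep(0.01, 4), impact = "plof", gene = "G0001",
                   seed = 24)
  q <- select_qualifying_plofs(p$variants, panel_frequencies(p))
  gl <- collapse_to_genelof(p, q)
  carrier_haps <- sum(gl$haplotypes_affected)
  per_variant <- panel_counts(p)$alt_haps
  expect_gte(carrier_haps, max(per_variant))
  expect_lte(carrier_haps, sum(per_variant))
})

test_that("the knockout catalogue counts individuals and genes exactly", {
  gl <- tibble::tibble(
    population = "p",
    individual = c("i1", "i2", "i3", "i3", "i4"),
    gene = c("A", "A", "B", "C", "A"),
    haplotypes_affected = c(2L, 2L, 2L, 2L, 1L),
    n_missing_sites = 0
  )
  cat <- build_knockout_catalogue(gl)
  expect_equal(cat$n_individuals_with_knockout, 3)
  expect_equal(cat$genes_knocked_out, c("A", "B", "C"))
  expect_equal(cat$genes_with_ge2_knockouts, "A")
  expect_equal(
    cat$per_individual$n_genes_knocked_out[cat$per_individual$individual == "i3"],
    2)
  g <- glance(cat)
  expect_equal(g$n_individuals_single_knockout, 2)
  empty <- build_knockout_catalogue(gl[gl$haplotypes_affected == 3, ])
  expect_equal(empty$n_individuals_with_knockout, 0)
  expect_length(empty$genes_knocked_out, 0)
})

test_that("the gene-based scan treats geneLOF as a biallelic unit", {
  # 795 heterozygous carrier haplotypes among 10,000 individuals puts the
  # expected knockout count at ~15.8; zero observed is a strong deficit
  gl <- tibble::tibble(
    population = "p", individual = sprintf("i%04d", 1:795),
    gene = "G1", haplotypes_affected = 1L, n_missing_sites = 0
  )
  s <- genelof_deficit_scan(gl, pop_sizes = c(p = 10000))
  expect_equal(s$lambda, 795^2 / 40000, tolerance = 1e-12)  # ~15.8
  expect_equal(s$observed, 0L)
  expect_true(s$strong_deficit)
  expect_lt(s$p_poisson, bonferroni_threshold(1258))

  # a neutral simulated gene stays inside the central Poisson band
  p <- quick_panel(50000, rep(0.008, 3), impact = "plof", gene = "G0001",
                   seed = 25)
  q <- select_qualifying_plofs(p$variants, panel_frequencies(p))
  sg <- genelof_deficit_scan(collapse_to_genelof(p, q))
  expect_gte(sg$observed, qpois(0.005, sg$lambda))
  expect_lte(sg$observed, qpois(0.995, sg$lambda))

  # a gene whose pLOFs were all filtered out is not tested at all
  empty <- collapse_to_genelof(p, q[0, ])
  expect_equal(nrow(genelof_deficit_scan(empty,
                                         pop_sizes = c(pop1 = 50000))), 0)
})

test_that("collapsing flags jointly lethal genes single variants cannot reach", {
  # four pLOFs with per-variant lambda ~ 0.9 (barely tested) collapse into a
  # gene with lambda ~ 14: removing knockouts is invisible per variant but
  # glaring per gene
  n <- 100000
  pv <- sqrt(0.9 / n)
  p <- quick_panel(n, rep(pv, 4), impact = "plof", gene = "G0001", seed = 26)
  q <- select_qualifying_plofs(p$variants, panel_frequencies(p))
  gl <- collapse_to_genelof(p, q)
  # joint lethality: erase the qualifying alleles of every knockout individual
  ko <- gl$individual[gl$haplotypes_affected == 2L]
  pop <- p$populations$pop1
  idx <- match(ko, pop$individuals)
  rows <- c(2L * idx - 1L, 2L * idx)
  p$populations$pop1$haps[rows, ] <- 0
  gl2 <- collapse_to_genelof(p, q)
  s_gene <- genelof_deficit_scan(gl2)
  s_var <- deficit_scan(p)
  expect_gte(s_gene$lambda, 5)
  expect_true(s_gene$strong_deficit)
  expect_true(all(s_var$lambda < 5))   # per-variant power is out of reach
})
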