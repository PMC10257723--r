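test_that("identical configuration and seed reproduce the panel exactly", {
  pops <- rbind(population_spec("a", 300, inbreeding_mean = 0.05),
                population_spec("b", 200))
  vars <- rbind(
    sim_variants(20, "intergenic", freq = seq(0.01, 0.2, length.out = 20),
                 populations = c("a", "b"), prefix = "int"),
    sim_variants(5, "plof", freq = 0.05, populations = c("a", "b"),
                 gene = "G0001", prefix = "lof")
  )
  cfg <- sim_config(pops, vars, gene_count = 3, seed = 77)
  p1 <- simulate_haplotype_panel(cfg)
  p2 <- simulate_haplotype_panel(cfg)
  expect_identical(p1$populations$a$haps, p2$populations$a$haps)
  expect_identical(p1$populations$b$haps, p2$populations$b$haps)
  expect_identical(p1$populations$a$ibd, p2$populations$a$ibd)
  # and the couple histories downstream
  gm <- assign_gene_structure(cfg)
  ch <- couple_history_config(n_couples = 100)
  h1 <- simulate_couple_histories(p1, gm, ch, "G0001", seed = 5)
  h2 <- simulate_couple_histories(p2, gm, ch, "G0001", seed = 5)
  expect_identical(h1, h2)
})

test_that("full identity-by-descent makes heterozygotes impossible", {
  p <- quick_panel(500, rep(0.5, 4), f = 1, seed = 3)
  cnt <- panel_counts(p)
  expect_true(all(cnt$alt_haps == 2 * cnt$hom))
  expect_true(all(cnt$alt_haps > 0))  # p = 0.5: carriers exist
})

test_that("zero-frequency variants yield an all-reference panel", {
  p <- quick_panel(200, c(0, 0, 0), f = 0.3, seed = 4)
  cnt <- panel_counts(p)
  expect_true(all(cnt$alt_haps == 0))
  expect_true(all(cnt$hom == 0))
})

test_that("simulator rejects invalid frequencies and empty populations", {
  expect_error(population_spec("a", 0), "n_individuals")
  expect_error(
    sim_config(population_spec("a", 10),
               sim_variants(1, "intergenic", freq = 0.7, populations = "a")),
    "frequencies"
  )
})

test_that("homozygote counts follow the HWE binomial law", {
  # p = 0.01, f = 0, n = 1e6: hom count ~ Poisson(100);
  # the mean over 20 seeds must sit within 100 +/- 3 * sqrt(100 / 20)
  homs <- vapply(1:20, function(seed) {
    p <- quick_panel(1e6, 0.01, seed = seed)
    panel_counts(p)$hom
  }, numeric(1))
  expect_lt(abs(mean(homs) - 100), 3 * sqrt(100 / 20))
})

test_that("recessive selection thins homozygotes by the survival fraction", {
  p <- quick_panel(20000, 0.05, impact = "plof", gene = "G0001", s = 1,
                   seed = 11)
  expect_identical(apply_recessive_selection(p, seed = 2)$populations$pop1$haps,
                   p$populations$pop1$haps)  # s = 1: identity

  # s = 0: no homozygotes survive
  p0 <- quick_panel(20000, 0.05, impact = "plof", gene = "G0001", s = 0,
                    seed = 12)
  expect_gt(panel_counts(p0)$hom, 0)
  after0 <- apply_recessive_selection(p0, seed = 2)
  expect_equal(panel_counts(after0)$hom, 0)

  # s = 0.1 with lambda ~ 50: mean observed ~ 5 across replicates,
  # and carrier frequencies approximately preserved
  obs <- vapply(1:10, function(seed) {
    pp <- quick_panel(20000, 0.05, impact = "plof", gene = "G0001", s = 0.1,
                      seed = 100 + seed)
    panel_counts(apply_recessive_selection(pp, seed = seed))$hom
  }, numeric(1))
  expect_lt(abs(mean(obs) - 5), 2.5)
  pp <- quick_panel(20000, 0.05, impact = "plof", gene = "G0001", s = 0.1,
                    seed = 200)
  freq_before <- panel_counts(pp)$alt_haps / (2 * 20000)
  freq_after <- panel_counts(apply_recessive_selection(pp, seed = 1))$alt_haps /
    (2 * 20000)
  expect_lt(abs(freq_after - freq_before) / freq_before, 0.1)
})

test_that("gene structure assignment is complete, exclusive and deterministic", {
  pops <- population_spec("a", 10)
  vars <- rbind(
    sim_variants(3, "plof", freq = 0.01, populations = "a", prefix = "lof"),
    sim_variants(2, "intergenic", freq = 0.01, populations = "a", prefix = "int")
  )
  cfg1 <- sim_config(pops, vars, gene_count = 1, seed = 5)
  gm <- assign_gene_structure(cfg1)
  expect_equal(unique(gm$gene[1:3]), "G0001")   # single gene: all pLOFs share it
  expect_true(all(is.na(gm$gene[4:5])))         # intergenic map to none
  expect_identical(gm, assign_gene_structure(cfg1))
  # round-trip through TSV is lossless
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(gm, path)
  back <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(gene = readr::col_character()))
  expect_equal(as.data.frame(back), as.data.frame(gm))
})

test_that("couple histories follow the Mendelian miscarriage model", {
  # one lethal gene at high carrier frequency so double-carrier couples
  # are plentiful
  p <- quick_panel(8000, 0.2, impact = "plof", gene = "G0001", seed = 21)
  cfg <- p$config
  gm <- assign_gene_structure(cfg)

  # pi = 0: double carriers miscarry at the background rate
  ch0 <- couple_history_config(n_couples = 3000,
                               background_miscarriage_rate = 0.1,
                               lethal_miscarriage_prob = 0)
  h0 <- simulate_couple_histories(p, gm, ch0, "G0001", seed = 31)
  dc <- h0[h0$truth_double_carrier, ]
  expect_gt(nrow(dc), 100)
  rate <- sum(dc$n_miscarriages) / sum(dc$n_pregnancies)
  expect_lt(abs(rate - 0.1), 0.04)

  # m0 = 0, pi = 1: double carriers miscarry one pregnancy in four
  ch1 <- couple_history_config(n_couples = 3000,
                               background_miscarriage_rate = 0,
                               lethal_miscarriage_prob = 1)
  h1 <- simulate_couple_histories(p, gm, ch1, "G0001", seed = 32)
  dc1 <- h1[h1$truth_double_carrier, ]
  rate1 <- sum(dc1$n_miscarriages) / sum(dc1$n_pregnancies)
  expect_lt(abs(rate1 - 0.25), 0.05)
  # non-double-carrier couples (including single carriers) stay at m0 = 0
  other <- h1[!h1$truth_double_carrier, ]
  expect_equal(sum(other$n_miscarriages), 0)
})

test_that("under the HWE null the observed/expected ratio centres on 1", {
  freqs <- sqrt(seq(20, 60, length.out = 250) / 30000)  # lambda in [20, 60]
  p <- quick_panel(30000, freqs, seed = 41)
  s <- deficit_scan(p)
  expect_true(all(s$tested))
  expect_lt(abs(mean(s$ratio) - 1), 0.03)
})
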