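# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher p by direct enumeration of the hypergeometric support:
# sum the null probabilities of all tables no more probable than the
# observed one (relative tolerance as is conventional for ties).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  s <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(s, m, n2, k)
  sum(pr[pr <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# Expected top-left cell of the noncentral hypergeometric at odds ratio psi.
nchg_mean_oracle <- function(psi, a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  s <- max(0, k - n2):min(k, m)
  lw <- stats::dhyper(s, m, n2, k, log = TRUE) + s * log(psi)
  w <- exp(lw - max(lw))
  sum(s * w) / sum(w)
}

# Brute-force scan statistics from genotype strings (one population).
brute_force_scan <- function(gt) {
  alleles <- do.call(rbind, strsplit(as.vector(gt), "|", fixed = TRUE))
  a1 <- matrix(as.integer(alleles[, 1]), nrow = nrow(gt))
  a2 <- matrix(as.integer(alleles[, 2]), nrow = nrow(gt))
  n <- nrow(gt)
  p <- colSums(a1 + a2) / (2 * n)
  list(p_hat = p, lambda = n * p^2, observed = colSums(a1 == 1 & a2 == 1))
}

# Random phased genotype-string matrix under HWE.
random_gt <- function(n, freqs) {
  sapply(freqs, function(p) {
    paste0(rbinom(n, 1, p), "|", rbinom(n, 1, p))
  }) |> matrix(nrow = n, dimnames = list(NULL, sprintf("v%03d", seq_along(freqs))))
}

# Small simulated cohort: one call wrapping config + panel.
quick_panel <- function(n, freqs, impact = "intergenic", f = 0, seed = 1,
                        gene = NA_character_, s = 1, pop = "pop1",
                        dispersion = 0) {
  pops <- population_spec(pop, n, inbreeding_mean = f,
                          inbreeding_dispersion = dispersion)
  vars <- sim_variants(length(freqs), impact, freq = freqs,
                       populations = pop, gene = gene, survival_fraction = s)
  cfg <- sim_config(pops, vars, gene_count = max(1, length(unique(gene))),
                    seed = seed,
                    allow_lethal_any = !all(impact %in% c("moderate", "plof")))
  simulate_haplotype_panel(cfg)
}
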