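# shared fixture builders -- everything generated in code, no stored data

tiny_panel <- function(n_sites = 5L, n_hap2_diffs = 3L) {
  make_default_panel(n_sites, n_hap2_diffs)
}

# one-stratum cohort with configurable size; returns sim list
tiny_cohort <- function(n_cases = 100L, n_controls = 100L, seed = 1L,
                        panel = make_default_panel(),
                        haplotype_or = c(HAP3 = 1.5, HAP1 = 0.7)) {
  spec <- cohort_spec(
    strata = data.frame(name = "EA", n_cases = as.integer(n_cases),
                        n_controls = as.integer(n_controls)),
    haplotype_or = haplotype_or, seed = seed
  )
  simulate_genotypes(panel, spec)
}

# independent brute-force MLE oracle for two-site haplotype frequencies:
# exhaustive 0.01-grid over the frequency simplex, closed-form genotype
# probabilities (no EM machinery shared with the implementation)
grid_mle_2site <- function(G, step = 0.01) {
  gr <- seq(0, 1, by = step)
  combo <- expand.grid(f11 = gr, f10 = gr, f01 = gr)
  combo$f00 <- 1 - combo$f11 - combo$f10 - combo$f01
  combo <- combo[combo$f00 >= -1e-9, , drop = FALSE]
  combo$f00[combo$f00 < 0] <- 0
  ll <- numeric(nrow(combo))
  for (i in seq_len(nrow(G))) {
    g <- G[i, ]
    p <- with(combo, switch(
      paste(g, collapse = ""),
      "00" = f00^2,        "01" = 2 * f01 * f00,
      "02" = f01^2,        "10" = 2 * f10 * f00,
      "11" = 2 * (f11 * f00 + f10 * f01),
      "12" = 2 * f11 * f01,
      "20" = f10^2,        "21" = 2 * f11 * f10,
      "22" = f11^2
    ))
    ll <- ll + log(pmax(p, 1e-300))
  }
  best <- combo[which.max(ll), ]
  c(`11` = best$f11, `10` = best$f10, `01` = best$f01, `00` = best$f00)
}

# independent exact-HWE oracle: enumerate every genotype table compatible
# with the observed allele counts and sum the (normalized) probabilities of
# tables no more probable than the observed one
hwe_exact_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  hs <- Filter(function(h) {
    naa <- (n_a - h) / 2
    (n_a - h) %% 2 == 0 && naa >= 0 && n - h - naa >= 0
  }, 0:n)
  pr <- vapply(hs, function(h) {
    naa <- (n_a - h) / 2
    nAA <- n - h - naa
    exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
          h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
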