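test_that("default panel has the nested distance structure", {
  p <- make_default_panel(19, 15)
  d <- function(a, b) sum(p$haplotypes[[a]] != p$haplotypes[[b]])
  expect_equal(d("HAP1", "HAP3"), 19)
  expect_equal(d("HAP1", "HAP2"), 15)
  expect_equal(d("HAP2", "HAP3"), 4)
  # nested-subset construction forces additivity
  expect_equal(d("HAP1", "HAP2") + d("HAP2", "HAP3"), d("HAP1", "HAP3"))
  # degenerate single-site panel: HAP2 equals HAP3
  p1 <- make_default_panel(1, 1)
  expect_equal(p1$haplotypes$HAP2, p1$haplotypes$HAP3)
  # per-stratum frequencies sum to 1
  for (f in p$freqs) expect_equal(sum(f), 1)
  expect_error(make_default_panel(19, 25), "n_hap2_diffs")
  expect_error(make_default_panel(0, 0), "n_sites")
})

test_that("case_frequencies applies the exact carrier-odds transform", {
  f <- c(HAP1 = 0.55, HAP2 = 0.35, HAP3 = 0.10)
  cf <- case_frequencies(f, c(HAP3 = 1.5))
  expect_equal(cf[["HAP3"]], 1 / 7, tolerance = 1e-12)  # 0.1111*1.5 odds
  expect_equal(sum(cf), 1)
  # the implied carrier OR is exact for every stated haplotype
  cf2 <- case_frequencies(f, c(HAP3 = 1.5, HAP1 = 0.7))
  or_of <- function(h) (cf2[[h]] / (1 - cf2[[h]])) / (f[[h]] / (1 - f[[h]]))
  expect_equal(or_of("HAP3"), 1.5, tolerance = 1e-12)
  expect_equal(or_of("HAP1"), 0.7, tolerance = 1e-12)
  expect_error(case_frequencies(f, c(NOPE = 2)), "unknown")
})

test_that("null simulation gives equal case/control frequencies; seeds reproduce", {
  p <- make_default_panel()
  sim <- tiny_cohort(5000, 5000, seed = 42, haplotype_or = c(HAP3 = 1))
  tr <- sim$truth
  for (h in c("HAP1", "HAP2", "HAP3")) {
    fc <- mean(c(tr$hap_a, tr$hap_b)[rep(tr$status, 2) == "case"] == h)
    fk <- mean(c(tr$hap_a, tr$hap_b)[rep(tr$status, 2) == "control"] == h)
    se <- sqrt(fk * (1 - fk) / (2 * 5000))
    expect_lt(abs(fc - fk), 3 * (se * sqrt(2)))
  }
  # control frequencies converge to panel frequencies (3 SE at n = 10^4 chromosomes)
  for (h in c("HAP1", "HAP2", "HAP3")) {
    fk <- mean(c(tr$hap_a, tr$hap_b)[rep(tr$status, 2) == "control"] == h)
    f0 <- p$freqs$EA[[h]]
    expect_lt(abs(fk - f0), 3 * sqrt(f0 * (1 - f0) / 10000))
  }
  # determinism
  sim2 <- tiny_cohort(5000, 5000, seed = 42, haplotype_or = c(HAP3 = 1))
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_identical(sim$truth, sim2$truth)
})

test_that("genotypes are always the sum of the two drawn haplotypes", {
  sim <- tiny_cohort(50, 50, seed = 3)
  H <- t(vapply(seq_len(nrow(sim$truth)), function(i) {
    as.integer(strsplit(sim$truth$allele_a[i], "")[[1]]) +
      as.integer(strsplit(sim$truth$allele_b[i], "")[[1]])
  }, integer(19)))
  expect_equal(unname(sim$genotypes), H)
})

test_that("expression simulator encodes the dose effect and DE structure", {
  sim <- tiny_cohort(60, 60, seed = 9)
  # noiseless: reference homozygote 10, risk homozygote 6 (40% lower)
  M <- simulate_expression(sim$truth, n_genes = 10, n_de_genes = 2,
                           noise_sd = 0, seed = 1)
  expect_equal(unname(M["TARGET", sim$truth$score == 0]),
               rep(10, sum(sim$truth$score == 0)))
  if (any(sim$truth$score == 4))
    expect_equal(unname(M["TARGET", sim$truth$score == 4]),
                 rep(6, sum(sim$truth$score == 4)))
  # no effect -> regression slope ~ 0
  M0 <- simulate_expression(sim$truth, n_genes = 10, n_de_genes = 2,
                            effect_per_score = 0, seed = 2)
  r <- cis_eqtl(M0["TARGET", ], sim$truth$score)
  expect_gt(r$p, 0.001)
  # DE genes: group mean ratio ~ de_fold at small noise
  M2 <- simulate_expression(sim$truth, n_genes = 50, n_de_genes = 5,
                            de_fold = 2, noise_sd = 0.05, seed = 3)
  is_case <- sim$truth$status == "case"
  ratio <- rowMeans(M2[sprintf("DE%03d", 1:5), is_case]) /
    rowMeans(M2[sprintf("DE%03d", 1:5), !is_case])
  expect_equal(unname(ratio), rep(2, 5), tolerance = 0.02)
})

test_that("serology simulator is seeded and shift-null gives equal groups", {
  # constructed truth with a sizeable risk-homozygote group
  truth <- data.frame(
    sample_id = sprintf("S%03d", 1:160),
    status = rep(c("case", "control"), 80),
    score = rep(c(4L, 0L), c(40L, 120L))
  )
  S1 <- simulate_serology(truth, shift = c(Sm = 1), seed = 7)
  S2 <- simulate_serology(truth, shift = c(Sm = 1), seed = 7)
  expect_identical(S1, S2)
  Sn <- normalize_nfi(S1)
  risk <- truth$score >= 4
  lr <- log(rowMeans(Sn[, risk]))
  lo <- log(rowMeans(Sn[, !risk]))
  expect_lt(max(abs(lr - lo)), 0.5)  # no systematic antigen shift
})
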