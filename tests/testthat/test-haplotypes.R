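test_that("EM equals direct counting when phase is unambiguous", {
  # homozygous samples only
  G <- rbind(c(0, 0, 0), c(2, 2, 2), c(2, 2, 2), c(0, 0, 0), c(0, 0, 0))
  tab <- em_haplotype_frequencies(G)
  expect_equal(tab$freq[tab$haplotype == "000"], 0.6, tolerance = 1e-9)
  expect_equal(tab$freq[tab$haplotype == "111"], 0.4, tolerance = 1e-9)
  expect_equal(sum(tab$expected_count), 10)
})

test_that("EM resolves the classic double-heterozygote with homozygote anchors", {
  # {AABB, aabb, AaBb} -> f(AB) = f(ab) = 0.5
  G <- rbind(c(0, 0), c(2, 2), c(1, 1))
  tab <- em_haplotype_frequencies(G)
  expect_equal(tab$freq[tab$haplotype == "00"], 0.5, tolerance = 1e-6)
  expect_equal(tab$freq[tab$haplotype == "11"], 0.5, tolerance = 1e-6)
  expect_true(all(!c("01", "10") %in% tab$haplotype) ||
                all(tab$freq[tab$haplotype %in% c("01", "10")] < 1e-5))
  expect_false(attr(tab, "low_confidence"))
})

test_that("all-double-heterozygote data sit at the symmetric saddle, flagged", {
  G <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  tab <- em_haplotype_frequencies(G)
  expect_equal(sort(tab$freq), rep(0.25, 4), tolerance = 1e-9)
  expect_true(attr(tab, "low_confidence"))
})

test_that("EM matches the brute-force likelihood-grid oracle on 2-site toys", {
  toys <- list(
    rbind(c(0, 0), c(2, 2), c(1, 1)),
    rbind(c(1, 0), c(1, 2), c(0, 1), c(2, 1)),
    rbind(c(2, 2), c(2, 2), c(1, 1), c(0, 0), c(1, 0)),
    rbind(c(0, 1), c(1, 1), c(2, 1), c(1, 0), c(1, 2), c(0, 0)),
    rbind(c(2, 0), c(0, 2), c(1, 1), c(1, 1))
  )
  for (k in seq_along(toys)) {
    G <- toys[[k]]
    tab <- em_haplotype_frequencies(G)
    mle <- grid_mle_2site(G)
    f_em <- setNames(rep(0, 4), c("11", "10", "01", "00"))
    f_em[tab$haplotype] <- tab$freq
    # grid resolution 0.01; saddle cases can have multiple MLEs with equal
    # likelihood, so compare likelihoods rather than raw frequencies
    ll <- function(f) {
      s <- 0
      for (i in seq_len(nrow(G))) {
        g <- paste(G[i, ], collapse = "")
        p <- switch(g,
          "00" = f[["00"]]^2, "01" = 2 * f[["01"]] * f[["00"]],
          "02" = f[["01"]]^2, "10" = 2 * f[["10"]] * f[["00"]],
          "11" = 2 * (f[["11"]] * f[["00"]] + f[["10"]] * f[["01"]]),
          "12" = 2 * f[["11"]] * f[["01"]],
          "20" = f[["10"]]^2, "21" = 2 * f[["11"]] * f[["10"]],
          "22" = f[["11"]]^2)
        s <- s + log(max(p, 1e-300))
      }
      s
    }
    # the EM optimum must attain (at least) the best grid likelihood
    expect_gte(ll(f_em), ll(mle) - 1e-6,
               label = sprintf("toy %d log-likelihood", k))
    # and land within a grid step of the grid argmax
    expect_equal(unname(f_em[names(mle)]), unname(mle), tolerance = 0.02,
                 label = sprintf("toy %d frequencies", k))
  }
})

test_that("EM marginalizes missing sites and excludes high-missingness samples", {
  G <- rbind(c(0, 0, 0), c(2, 2, 2), c(0, NA, 0), c(NA, NA, NA))
  expect_warning(tab <- em_haplotype_frequencies(G, max_missing = 0.5),
                 "missing")
  expect_equal(attr(tab, "n_samples"), 3L)
  expect_equal(sum(tab$expected_count), 6)
  expect_gt(tab$freq[tab$haplotype == "000"], 0.6)  # missing site imputed 0
})

test_that("ld_pair reproduces closed forms and symmetry", {
  # perfect coupling
  r <- ld_pair(0.5, 0, 0, 0.5)
  expect_equal(r$Dprime, 1); expect_equal(r$r2, 1)
  # independence
  r0 <- ld_pair(0.25, 0.25, 0.25, 0.25)
  expect_equal(r0$Dprime, 0); expect_equal(r0$r2, 0)
  # closed form with pA = pB = 0.5
  r1 <- ld_pair(0.4, 0.1, 0.1, 0.4)
  expect_equal(r1$D, 0.15); expect_equal(r1$Dprime, 0.6)
  expect_equal(r1$r2, 0.36)
  # relabelling both sites simultaneously (f11<->f00, f10<->f01) leaves
  # D' and r2 unchanged; check on an asymmetric table
  ra <- ld_pair(0.5, 0.2, 0.1, 0.2)
  rb <- ld_pair(0.2, 0.1, 0.2, 0.5)
  expect_equal(ra$Dprime, rb$Dprime)
  expect_equal(ra$r2, rb$r2)
  # monomorphic flag
  expect_true(ld_pair(0, 0, 0.5, 0.5)$monomorphic)
})

test_that("select_tag_set keeps the peak and the panel sites in perfect LD", {
  sim <- tiny_cohort(250, 250, seed = 17)
  tags <- select_tag_set(sim$genotypes, "snp10", threshold = 0.8)
  expect_true("snp10" %in% tags$variant_id)
  # three-haplotype construction puts every site in strong LD with the peak
  expect_equal(nrow(tags), 19)
  # unreachable threshold keeps only the peak
  t2 <- select_tag_set(sim$genotypes, "snp10", threshold = 1.01)
  expect_equal(t2$variant_id, "snp10")
})

test_that("label_haplotypes is Hamming-nearest with OTHER fallback", {
  p <- make_default_panel(5, 3)
  labs <- label_haplotypes(c("00000", "11100", "11111", "10000", "01011"), p,
                           max_mismatch = 1)
  expect_equal(labs, c("HAP1", "HAP2", "HAP3", "HAP1", "OTHER"))
  # tie (distance 2 to several) breaks to the lexicographically first label
  p1 <- make_default_panel(1, 1)   # HAP2 == HAP3 at one site
  expect_equal(label_haplotypes("1", p1), "HAP2")
})

test_that("haplotype association recovers per-haplotype odds ratios", {
  panel <- make_default_panel()
  spec <- cohort_spec(
    strata = data.frame(name = c("EA", "AA", "AS"),
                        n_cases = 800L, n_controls = 800L),
    haplotype_or = c(HAP3 = 1.5, HAP1 = 0.7), seed = 23
  )
  sim <- simulate_genotypes(panel, spec)
  freqs <- stratified_haplotype_frequencies(sim$genotypes, sim$samples, panel)
  ha <- haplotype_assoc(freqs)
  expect_gt(ha$or_mh[ha$label == "HAP3"], 1.2)
  expect_lt(ha$or_mh[ha$label == "HAP3"], 1.9)
  expect_gt(ha$or_mh[ha$label == "HAP1"], 0.55)
  expect_lt(ha$or_mh[ha$label == "HAP1"], 0.85)
  # frequencies per stratum/group sum to 1 and counts to 2N
  for (st in c("EA", "AA", "AS")) for (g in c("case", "control")) {
    sel <- freqs$stratum == st & freqs$status == g
    expect_equal(sum(freqs$freq[sel]), 1, tolerance = 1e-6)
    # pruning of sub-1e-6 haplotypes can shave a whisker off the total
    expect_equal(sum(freqs$expected_count[sel]), 2 * 800, tolerance = 1e-4)
  }
})

test_that("diplotype_dose reproduces the reference-contrast OR and trend", {
  # printed-count arithmetic: 34/400 vs 20/400 -> OR 1.7
  asn <- data.frame(
    status = rep(c("case", "control", "case", "control"),
                 c(34L, 400L, 20L, 400L)),
    hap_a = rep(c("HAP3", "HAP3", "HAP1", "HAP1"), c(34L, 400L, 20L, 400L)),
    hap_b = rep(c("HAP3", "HAP3", "HAP1", "HAP1"), c(34L, 400L, 20L, 400L)),
    score = rep(c(4L, 4L, 0L, 0L), c(34L, 400L, 20L, 400L))
  )
  dd <- diplotype_dose(asn)
  expect_equal(dd$per_diplotype$or_[dd$per_diplotype$diplotype == "HAP3/HAP3"],
               1.7, tolerance = 1e-12)
  expect_gt(dd$trend$slope, 0)
  # multiplicative per-haplotype OR 1.5: OR(HAP3/HAP3) > OR(HAP1/HAP3) > 1
  sim <- tiny_cohort(2500, 2500, seed = 29,
                     haplotype_or = c(HAP3 = 1.5))
  dip <- assign_diplotypes(sim$genotypes, sim$samples, make_default_panel())
  dd2 <- diplotype_dose(dip)
  or_of <- function(k) dd2$per_diplotype$or_[dd2$per_diplotype$diplotype == k]
  expect_gt(or_of("HAP3/HAP3"), or_of("HAP1/HAP3"))
  expect_gt(or_of("HAP1/HAP3"), 1)
  # absent reference is an error
  asn2 <- asn[asn$hap_a != "HAP1", ]
  expect_error(diplotype_dose(asn2), "HAP1/HAP1")
})
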