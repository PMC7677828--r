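test_that("allelic_test matches closed-form arithmetic and handles zeros", {
  r <- allelic_test(30, 170, 15, 185)
  expect_equal(r$or_, (30 * 185) / (170 * 15), tolerance = 1e-12)  # 2.176
  expect_equal(r$chi2, 400 * (30 * 185 - 170 * 15)^2 /
                 (200 * 200 * 45 * 355), tolerance = 1e-12)        # 5.634
  expect_equal(round(r$or_, 3), 2.176)
  expect_equal(round(r$chi2, 3), 5.634)
  # identical groups
  r0 <- allelic_test(20, 180, 20, 180)
  expect_equal(r0$or_, 1)
  expect_equal(r0$chi2, 0)
  # zero cell -> Haldane-Anscombe correction, finite OR inside the CI
  rz <- allelic_test(0, 100, 10, 90)
  expect_true(is.finite(rz$or_) && rz$or_ > 0)
  expect_true(rz$ci95[1] <= rz$or_ && rz$or_ <= rz$ci95[2])
  # empty margin -> untestable
  expect_true(allelic_test(0, 0, 10, 90)$untestable)
  # relabelling alt/ref in both groups inverts the OR and keeps chi2;
  # chi2 is also invariant to a single-group row swap
  r1 <- allelic_test(30, 170, 15, 185)
  r2 <- allelic_test(170, 30, 185, 15)
  expect_equal(r2$or_, 1 / r1$or_, tolerance = 1e-12)
  expect_equal(r2$chi2, r1$chi2, tolerance = 1e-12)
})

test_that("genomic control uses the median-chi2 estimator, never deflates", {
  expect_equal(genomic_control(rep(0.4549364, 5))$lambda_, 1, tolerance = 1e-4)
  # median chi2 = 1.3647 -> lambda ~ 3.0
  lam <- genomic_control(c(1, 1.3647, 2))$lambda_
  expect_equal(lam, 3.0, tolerance = 0.001)
  # corrected statistic and p
  co <- apply_genomic_control(9, 3)
  expect_equal(co$chi2_gc, 3)
  expect_equal(co$p_gc, pchisq(3, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(co$p_gc, 4), 0.0833)
  # lambda < 1 leaves statistics unchanged
  expect_equal(apply_genomic_control(9, 0.5)$chi2_gc, 9)
  expect_error(genomic_control(numeric(0)), "no chi")
})

test_that("bh_fdr equals the step-up rule and p.adjust oracle", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.04)), c(0.003, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  set.seed(21)
  for (rep in 1:5) {
    p <- runif(50)^2
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, "BH"))      # independent reference
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  # order preserved, NAs passed through
  p <- c(0.5, NA, 0.01)
  expect_true(is.na(bh_fdr(p)[2]))
})

test_that("cmh_test matches closed form, reductions, and mantelhaen.test", {
  # single stratum reduces to the allelic 2x2 OR
  t1 <- c(30, 170, 15, 185)
  expect_equal(cmh_test(list(t1))$or_mh, allelic_test(30, 170, 15, 185)$or_,
               tolerance = 1e-12)
  # hand-derived Mantel-Haenszel closed form
  r <- cmh_test(list(c(20, 80, 10, 90), c(30, 70, 15, 85)))
  expect_equal(r$or_mh, 21.75 / 9.25, tolerance = 1e-10)
  expect_equal(round(r$or_mh, 3), 2.351)
  # identical null strata
  r0 <- cmh_test(list(c(10, 90, 10, 90), c(10, 90, 10, 90)))
  expect_equal(r0$or_mh, 1)
  expect_equal(r0$chi2_cmh, 0)
  # K copies of a table give the same OR as one copy
  expect_equal(cmh_test(rep(list(t1), 4))$or_mh, cmh_test(list(t1))$or_mh)
  # agreement with stats::mantelhaen.test (no continuity correction)
  tabs <- list(c(25, 120, 14, 150), c(40, 60, 22, 90), c(9, 51, 13, 44))
  arr <- array(unlist(lapply(tabs, function(v) matrix(v, 2, byrow = TRUE))),
               dim = c(2, 2, 3))
  mh <- mantelhaen.test(arr, correct = FALSE)
  ours <- cmh_test(tabs)
  expect_equal(ours$or_mh, unname(mh$estimate), tolerance = 1e-9)
  expect_equal(ours$chi2_cmh, unname(mh$statistic), tolerance = 1e-9)
  expect_equal(ours$p, mh$p.value, tolerance = 1e-9)
  expect_error(cmh_test(list()), "stratum")
})

test_that("assoc_scan corrects with lambda and orders FDR against raw p", {
  sim <- tiny_cohort(300, 300, seed = 13)
  sc <- assoc_scan(sim$genotypes, sim$samples)
  expect_true(all(sc$p_fdr >= sc$p_gc - 1e-15, na.rm = TRUE))
  expect_true(attr(sc, "lambda_") > 0)
  # risk site (alt allele rides HAP2/HAP3) should trend OR > 1 at site 16+?
  # site 19 alt allele is specific to HAP3 (OR 1.5 world)
  expect_gt(sc$or_[19], 1)
})

test_that("conditional_scan removes signal explained by the peak and keeps independent signal", {
  set.seed(31)
  n <- 400
  causal <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  # perfect proxy and an independent null variant
  proxy <- causal
  null_v <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  risk <- plogis(-0.6 + 0.9 * causal)
  status <- ifelse(runif(n) < risk, "case", "control")
  G <- cbind(causal = causal, proxy = proxy, null_v = null_v)
  rownames(G) <- sprintf("s%d", 1:n)
  samples <- data.frame(sample_id = rownames(G), status = status,
                        stratum = "EA")
  # conditioning on the causal variant: proxy loses all signal
  cond <- conditional_scan(G, samples, "causal")
  expect_true(cond$untestable[cond$variant_id == "proxy"] ||
                cond$chi2_cmh[cond$variant_id == "proxy"] < 1e-9)
  # conditioning on the independent null variant: causal signal survives
  raw_p <- cmh_scan(G[, "causal", drop = FALSE], samples)$p
  cond2 <- conditional_scan(G, samples, "null_v")
  expect_lt(cond2$p[cond2$variant_id == "causal"], min(1, raw_p * 10))
  # monomorphic peak is an error
  G2 <- cbind(G, mono = rep(1L, n))
  expect_error(conditional_scan(G2, samples, "mono"), "monomorphic")
})
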