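# lognormal expression fixture: gene means span a range and noise is
# multiplicative (constant log-scale variance), so the reference profile has
# spread and the F-test operates on comparable per-gene variances
make_expr <- function(n_genes, n_samples, sdlog = 0.1, seed = 1,
                      means = NULL) {
  set.seed(seed)
  if (is.null(means)) means <- exp(seq(log(5), log(50), length.out = n_genes))
  M <- means * matrix(exp(rnorm(n_genes * n_samples, 0, sdlog)), n_genes)
  rownames(M) <- sprintf("g%04d", seq_len(n_genes))
  colnames(M) <- sprintf("s%02d", seq_len(n_samples))
  M
}

test_that("reference group keeps stable genes and drops high-variance ones", {
  M <- make_expr(90, 10, sdlog = 0.1, seed = 61)
  noisy <- make_expr(10, 10, sdlog = 0.1 * sqrt(10), seed = 161,
                     means = rep(20, 10))
  rownames(noisy) <- sprintf("noisy%02d", 1:10)
  ref <- build_reference_group(rbind(M, noisy))
  expect_length(intersect(rownames(noisy), ref$reference_genes), 0)
  expect_gt(length(intersect(ref$reference_genes, rownames(M))), 70)
  expect_gt(ref$tech_variance, 0)
  # genes below background never enter candidacy
  M2 <- rbind(M, low = rep(1.5, 10))
  ref2 <- build_reference_group(M2)
  expect_false("low" %in% ref2$reference_genes)
  # all genes from one distribution: nearly all retained
  M3 <- make_expr(100, 10, seed = 62)
  ref3 <- build_reference_group(M3)
  expect_gt(length(ref3$reference_genes), 85)
  # pool size = reference genes x samples
  expect_equal(length(ref3$residual_pool),
               length(ref3$reference_genes) * 10)
  expect_error(build_reference_group(M[, 1:2]), "3 control samples")
})

test_that("reference-group construction is order-independent and terminates", {
  M <- make_expr(80, 8, seed = 63)
  M[1:8, ] <- M[1:8, ] * exp(matrix(rnorm(64, 0, 0.5), 8))
  r1 <- build_reference_group(M)
  r2 <- build_reference_group(M[sample(nrow(M)), ])
  expect_setequal(r1$reference_genes, r2$reference_genes)
})

test_that("two_step_normalize collapses scalar multiples and affine distortion", {
  M <- make_expr(200, 6, seed = 64)
  ref <- build_reference_group(M)
  # sample B = 2 x sample A: near-identical after step 1 (exact up to the
  # pseudo-floor in the log transform)
  M2 <- cbind(M, B = 2 * M[, 1])
  N2 <- two_step_normalize(M2, ref)
  expect_lt(max(abs(N2[, "B"] - N2[, 1])), 0.01)
  # idempotence: renormalizing the back-transformed output is stable
  N <- two_step_normalize(M, ref)
  N_again <- two_step_normalize(2^N - 0.1, ref)
  expect_lt(max(abs(N - N_again)), 1e-9)
  # constructed per-sample affine distortion on the log scale is removed
  L <- hapcohort:::de_log(M, 0.1)
  distorted <- 2^(3 + 2 * L) - 0.1
  Nd <- two_step_normalize(distorted, ref)
  expect_lt(max(abs(Nd - N)), 1e-6)
})

test_that("associative_t_test behaves at null, shift, and degenerate inputs", {
  set.seed(65)
  pool <- rnorm(1000, 0, 0.2)
  # null residuals -> roughly uniform p
  p_null <- replicate(300, associative_t_test(rnorm(6, 0, 0.2), pool))
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.10)
  # 5-pool-SD shift with 6 replicates is overwhelming
  expect_lt(associative_t_test(rnorm(6, 5 * 0.2, 0.2), pool), 1e-4)
  # residuals at the pool mean
  expect_gt(associative_t_test(rep(mean(pool), 3) + rnorm(3, 0, 1e-8), pool),
            0.9)
  # degenerate zero-variance agreement
  expect_equal(associative_t_test(rep(0, 3), rep(0, 150)), 1)
  expect_equal(associative_t_test(rep(1, 3), rep(0, 150)), 0)
  expect_error(associative_t_test(1, pool), "replicates")
  expect_error(associative_t_test(c(1, 2), rnorm(10)), "pool")
})

test_that("run_de recovers planted genes, rejects sub-fold genes, is monotone in fold", {
  Mk <- make_expr(1000, 10, seed = 66)
  Mc <- make_expr(1000, 6, seed = 67)
  planted <- sprintf("g%04d", seq(50, 1000, by = 50))   # 20 genes
  Mc[planted, ] <- Mc[planted, ] * 2                    # fold 2
  de <- run_de(Mc, Mk)
  expect_gte(sum(de$passed[de$gene %in% planted]), 18)
  expect_equal(sum(de$passed[!de$gene %in% planted]), 0)
  # sub-threshold fold genes are excluded regardless of p
  Mc2 <- make_expr(1000, 6, seed = 68)
  Mc2[planted, ] <- Mc2[planted, ] * 1.25
  de2 <- run_de(Mc2, Mk)
  expect_false(any(de2$passed[de2$gene %in% planted]))
  expect_true(all(grepl("fold", de2$fail_reason[de2$gene %in% planted])))
  # monotonicity: raising a planted gene's fold never removes it
  Mc3 <- Mc
  Mc3[planted[1], ] <- Mc[planted[1], ] * 2
  de3 <- run_de(Mc3, Mk)
  expect_true(de3$passed[de3$gene == planted[1]])
})

test_that("null pipeline passes essentially nothing", {
  Mk <- make_expr(1000, 10, seed = 69)
  Mc <- make_expr(1000, 6, seed = 70)
  de <- run_de(Mc, Mk)
  expect_lte(sum(de$passed), 1)
})
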