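# Internal-standards differential expression: a reference group of stable
# genes calibrates technical variance; candidate genes must pass both a
# replicate Student t test and an "associative" t test of their residuals
# against the pooled reference residuals, plus expression and fold filters.

#' Differential-expression configuration
#'
#' @param background_rpkm minimal mean expression (default 2 RPKM).
#' @param t_alpha replicate Student-t selection level (default 0.05).
#' @param assoc_alpha associative-t threshold (default 1e-4).
#' @param min_fold fold-change floor, un-logged group-mean ratio
#'   (default 1.5).
#' @param f_alpha reference-group F-test level (default 0.05).
#' @param pseudo_floor RPKM floor used in fold computation (default 0.1).
#' @return a `de_config` list.
#' @export
de_config <- function(background_rpkm = 2, t_alpha = 0.05,
                      assoc_alpha = 1e-4, min_fold = 1.5, f_alpha = 0.05,
                      pseudo_floor = 0.1) {
  stopifnot(background_rpkm >= 0, t_alpha > 0, t_alpha < 1,
            assoc_alpha > 0, assoc_alpha < 1, min_fold > 0,
            f_alpha > 0, f_alpha < 1, pseudo_floor > 0)
  structure(list(background_rpkm = background_rpkm, t_alpha = t_alpha,
                 assoc_alpha = assoc_alpha, min_fold = min_fold,
                 f_alpha = f_alpha, pseudo_floor = pseudo_floor),
            class = "de_config")
}

# log2 working scale for the internal-standards machinery
de_log <- function(M, floor = 0.1) log2(M + floor)

row_vars <- function(M) {
  mu <- rowMeans(M)
  rowSums((M - mu)^2) / (ncol(M) - 1L)
}

#' Build the reference gene group (internal standard)
#'
#' Candidate genes are those expressed above background; genes whose
#' variance (on the log2 scale, after per-sample median alignment) is
#' significantly larger than the pooled candidate variance by a one-sided F
#' test are dropped, iterating until the set is stable.  The surviving genes
#' act as an internal standard of equal expression whose residuals estimate
#' technical variance.
#'
#' @param M_ctrl genes x samples RPKM matrix of the control group
#'   (>= 3 samples).
#' @param cfg a [de_config()].
#' @param min_genes minimum surviving reference genes (default 20); fewer is
#'   an error because the residual pool can no longer calibrate the
#'   associative test.
#' @return a `reference_model`: list with `reference_genes`,
#'   `residual_pool` (flat vector of gene-centred log2 residuals),
#'   `tech_variance`, `gene_means` (log2 scale) and `sample_medians`.
#' @export
build_reference_group <- function(M_ctrl, cfg = de_config(), min_genes = 20L) {
  if (ncol(M_ctrl) < 3L) stop_arg("need >= 3 control samples")
  candidates <- rownames(M_ctrl)[rowMeans(M_ctrl) > cfg$background_rpkm]
  if (length(candidates) < min_genes)
    stop_arg("fewer than ", min_genes, " genes above background")
  L <- de_log(M_ctrl, cfg$pseudo_floor)
  # per-sample median alignment over the candidate pool (step-1 analogue)
  med <- apply(L[candidates, , drop = FALSE], 2L, stats::median)
  L <- sweep(L, 2L, med - mean(med))
  n <- ncol(L)
  repeat {
    v <- row_vars(L[candidates, , drop = FALSE])
    pooled <- mean(v)
    f_crit <- stats::qf(1 - cfg$f_alpha, df1 = n - 1L,
                        df2 = (n - 1L) * (length(candidates) - 1L))
    drop <- v / pooled > f_crit
    if (!any(drop)) break
    candidates <- candidates[!drop]
    if (length(candidates) < min_genes)
      stop_arg("reference group shrank below ", min_genes, " genes")
  }
  R <- L[candidates, , drop = FALSE]
  mu <- rowMeans(R)
  resid <- as.numeric(R - mu)
  structure(list(reference_genes = candidates, residual_pool = resid,
                 tech_variance = stats::var(resid), gene_means = mu,
                 sample_medians = med),
            class = "reference_model")
}

#' Two-step normalization against a reference model
#'
#' Step 1 scales each sample so its median over the reference genes is
#' equal across samples (a per-sample shift on the log2 scale).  Step 2 fits
#' each sample's reference-gene profile on the across-sample mean reference
#' profile and inverts the fitted affine distortion for all genes.  The
#' procedure is idempotent.
#'
#' @param M genes x samples RPKM matrix.
#' @param ref a `reference_model`; reference genes missing from `M` are
#'   dropped with a warning.
#' @param pseudo_floor RPKM floor for the log transform.
#' @return normalized genes x samples matrix on the log2 scale.
#' @export
two_step_normalize <- function(M, ref, pseudo_floor = 0.1) {
  genes <- intersect(ref$reference_genes, rownames(M))
  if (length(genes) < length(ref$reference_genes))
    warning("using ", length(genes), "/", length(ref$reference_genes),
            " reference genes present in the matrix")
  if (length(genes) < 3L) stop_arg("too few reference genes present")
  L <- de_log(M, pseudo_floor)
  med <- apply(L[genes, , drop = FALSE], 2L, stats::median)
  L <- sweep(L, 2L, med - mean(med))
  # regress on the model's fixed mean reference profile: this makes the
  # two-step procedure exactly idempotent (a rerun fits slope 1 and an
  # intercept equal to the step-1 shift, which step 2 then removes)
  target <- ref$gene_means[genes]
  for (s in seq_len(ncol(L))) {
    y <- L[genes, s]
    fit <- stats::lm.fit(cbind(1, target), y)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    ssy <- sum((y - mean(y))^2)
    r2 <- if (ssy > 0) 1 - sum(fit$residuals^2) / ssy else NA_real_
    if (is.na(b) || b <= 0 || !is.finite(r2) || r2 < 0.3) {
      # flat reference profile: the slope is unidentifiable, remove the
      # per-sample shift only
      b <- 1; a <- mean(y) - mean(target)
    }
    L[, s] <- (L[, s] - a) / b
  }
  L
}

#' Associative t test against the reference residual pool
#'
#' Two-sample Student t (pooled variance) comparing a gene's replicated
#' residuals -- deviations of the experimental replicates from the averaged
#' control profile -- with the entire reference residual pool.
#'
#' @param residuals numeric vector of >= 2 experimental residuals.
#' @param pool reference residual pool (>= 100 values).
#' @return two-sided p-value.
#' @export
associative_t_test <- function(residuals, pool) {
  if (length(residuals) < 2L) stop_arg("need >= 2 experimental replicates")
  if (length(pool) < 100L) stop_arg("residual pool too small (< 100)")
  n1 <- length(residuals); n2 <- length(pool)
  v1 <- stats::var(residuals); v2 <- stats::var(pool)
  if (v1 == 0 && v2 == 0)
    return(if (mean(residuals) == mean(pool)) 1 else 0)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (mean(residuals) - mean(pool)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
}

# vectorized pooled-variance Student t across rows of two matrices
row_t_test <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- row_vars(A); v2 <- row_vars(B)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[sp2 == 0 & m1 == m2] <- 1
  p[sp2 == 0 & m1 != m2] <- 0
  list(t = tstat, p = p)
}

#' Run the internal-standards differential-expression pipeline
#'
#' Reference group from the control matrix, two-step normalization of all
#' samples, per-gene replicate Student t (`p_t`), associative t of the
#' case residuals against the reference pool (`p_assoc`), then the
#' expression-floor and fold filters.  A gene passes iff
#' `p_t < t_alpha`, `p_assoc < assoc_alpha`, `fold > min_fold` and
#' mean RPKM > `background_rpkm`.
#'
#' @param M_case,M_ctrl genes x samples RPKM matrices (same genes;
#'   >= 2 case and >= 3 control samples).
#' @param cfg a [de_config()].
#' @return data.frame, one row per gene: gene, mean_rpkm, fold, p_t,
#'   p_assoc, passed, fail_reason; the `reference_model` is attached as an
#'   attribute.
#' @export
run_de <- function(M_case, M_ctrl, cfg = de_config()) {
  if (ncol(M_case) < 2L) stop_arg("need >= 2 case samples")
  if (!identical(rownames(M_case), rownames(M_ctrl)))
    stop_arg("case and control matrices must share the same genes")
  ref <- build_reference_group(M_ctrl, cfg)
  Nc <- two_step_normalize(M_case, ref, cfg$pseudo_floor)
  Nk <- two_step_normalize(M_ctrl, ref, cfg$pseudo_floor)
  tt <- row_t_test(Nc, Nk)
  ctrl_profile <- rowMeans(Nk)
  resid_case <- Nc - ctrl_profile
  pool <- ref$residual_pool
  n1 <- ncol(Nc); n2 <- length(pool)
  m1 <- rowMeans(resid_case); v1 <- row_vars(resid_case)
  m2 <- mean(pool); v2 <- stats::var(pool)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_assoc <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_assoc <- 2 * stats::pt(abs(t_assoc), df = n1 + n2 - 2, lower.tail = FALSE)
  mean_rpkm <- rowMeans(cbind(M_case, M_ctrl))
  fold_raw <- (rowMeans(M_case) + cfg$pseudo_floor) /
    (rowMeans(M_ctrl) + cfg$pseudo_floor)
  fold <- pmax(fold_raw, 1 / fold_raw)    # symmetric up/down fold
  passed <- tt$p < cfg$t_alpha & p_assoc < cfg$assoc_alpha &
    fold > cfg$min_fold & mean_rpkm > cfg$background_rpkm
  fail <- rep(NA_character_, nrow(M_case))
  fail[!passed] <- apply(cbind(tt$p >= cfg$t_alpha,
                               p_assoc >= cfg$assoc_alpha,
                               fold <= cfg$min_fold,
                               mean_rpkm <= cfg$background_rpkm)[!passed, ,
                                                                 drop = FALSE],
                         1L, function(z)
                           paste(c("t_test", "assoc_test", "fold",
                                   "background")[z], collapse = ";"))
  out <- data.frame(gene = rownames(M_case), mean_rpkm = mean_rpkm,
                    fold = fold_raw, p_t = tt$p, p_assoc = p_assoc,
                    passed = passed, fail_reason = fail,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference_model") <- ref
  out
}
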