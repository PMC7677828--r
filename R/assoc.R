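#' Allelic case-control association test on a 2x2 allele-count table
#'
#' Pearson chi-square on the 2x2 table of alternate/reference allele counts
#' in cases vs controls, with the odds ratio `ad/bc` (Haldane-Anscombe +0.5
#' on all cells when any cell is zero) and a Woolf 95% confidence interval on
#' the log odds ratio.
#'
#' @param case_alt,case_ref,ctrl_alt,ctrl_ref allele counts.
#' @return list of class `assoc_result`: `table`, `or_`, `ci95`, `chi2`,
#'   `p_raw`, `untestable` (TRUE when a margin is empty).
#' @export
allelic_test <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  a <- as.numeric(case_alt); b <- as.numeric(case_ref)
  c <- as.numeric(ctrl_alt); d <- as.numeric(ctrl_ref)
  if (any(c(a, b, c, d) < 0)) stop_arg("counts must be >= 0")
  n <- a + b + c + d
  if (n == 0) stop_arg("empty table")
  tab <- matrix(c(a, b, c, d), 2L, byrow = TRUE,
                dimnames = list(c("case", "control"), c("alt", "ref")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(table = tab, or_ = NA_real_, ci95 = c(NA, NA),
                          chi2 = NA_real_, p_raw = NA_real_, untestable = TRUE),
                     class = "assoc_result"))
  }
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or_ <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(or_) + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(table = tab, or_ = or_, ci95 = ci, chi2 = chi2,
                 p_raw = p, untestable = FALSE),
            class = "assoc_result")
}

#' Genomic-control inflation factor
#'
#' The median-based estimator: lambda = median(chi2) / qchisq(0.5, 1)
#' (constant 0.4549364).
#'
#' @param chi2_values numeric vector of 1-df chi-square statistics.
#' @return list with `lambda_` and `n_tests`.
#' @export
genomic_control <- function(chi2_values) {
  chi2_values <- chi2_values[!is.na(chi2_values)]
  if (length(chi2_values) == 0L) stop_arg("no chi-square statistics supplied")
  list(lambda_ = stats::median(chi2_values) / stats::qchisq(0.5, df = 1),
       n_tests = length(chi2_values))
}

#' Apply genomic control to a chi-square statistic
#'
#' Divides the statistic by lambda when lambda > 1 (no deflation is applied
#' when lambda <= 1) and returns the corrected 1-df p-value.
#'
#' @param chi2 statistic(s).
#' @param lambda_ inflation factor.
#' @return list with `chi2_gc` and `p_gc`.
#' @export
apply_genomic_control <- function(chi2, lambda_) {
  if (lambda_ <= 0) stop_arg("`lambda_` must be > 0")
  chi2_gc <- if (lambda_ > 1) chi2 / lambda_ else chi2
  list(chi2_gc = chi2_gc,
       p_gc = stats::pchisq(chi2_gc, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `m * p / rank` with monotonicity enforced by a
#' cumulative minimum from the largest p downward; output order matches the
#' input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq.int(m, 1L) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Cochran-Mantel-Haenszel stratified 2x2 test
#'
#' Combines per-stratum 2x2 allele-count tables (rows case/control, columns
#' alt/ref) into the Mantel-Haenszel common odds ratio
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` and the CMH chi-square
#' `(|sum(a_i - E[a_i])|)^2 / sum(Var(a_i))`, by default without continuity
#' correction, with a 1-df p-value.
#'
#' @param tables list of 2x2 matrices or of numeric vectors
#'   `c(a, b, c, d)` = (case_alt, case_ref, ctrl_alt, ctrl_ref).
#' @param continuity subtract 0.5 from |sum(a - E(a))| before squaring
#'   (default FALSE).
#' @return list of class `cmh_result`: `or_mh`, `chi2_cmh`, `p`,
#'   `n_strata`, `strata_tables`.
#' @export
cmh_test <- function(tables, continuity = FALSE) {
  if (length(tables) == 0L) stop_arg("at least one stratum required")
  tabs <- lapply(tables, function(t) {
    v <- as.numeric(t)
    if (length(v) != 4L || any(v < 0)) stop_arg("each stratum must be a 2x2 count table")
    if (is.matrix(t)) c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]) else v
  })
  usable <- vapply(tabs, function(v) sum(v) > 0, TRUE)
  if (!any(usable)) stop_arg("all strata are empty")
  tabs <- tabs[usable]
  num <- den <- dev <- vr <- 0
  for (v in tabs) {
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
    n <- a + b + c + d
    num <- num + a * d / n
    den <- den + b * c / n
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    dev <- dev + (a - r1 * c1 / n)
    if (n > 1) vr <- vr + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  or_mh <- if (den > 0) num / den else Inf
  absdev <- abs(dev)
  if (continuity) absdev <- max(0, absdev - 0.5)
  chi2 <- if (vr > 0) absdev^2 / vr else 0
  structure(list(or_mh = or_mh, chi2_cmh = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n_strata = length(tabs),
                 strata_tables = tabs),
            class = "cmh_result")
}

# per-variant 2x2 allele-count table from genotype codes
allele_table <- function(g, is_case) {
  gc_case <- g[is_case & !is.na(g)]
  gc_ctrl <- g[!is_case & !is.na(g)]
  c(sum(gc_case), 2 * length(gc_case) - sum(gc_case),
    sum(gc_ctrl), 2 * length(gc_ctrl) - sum(gc_ctrl))
}

#' Genome-wide allelic scan with genomic control and FDR
#'
#' Runs [allelic_test()] on every variant, estimates the genomic-control
#' inflation factor on the chosen variant class, and returns raw, corrected
#' and BH-FDR-adjusted p-values.
#'
#' @param G samples x variants 0/1/2 matrix.
#' @param samples sample sheet (needs `status`).
#' @param lambda_on `"common"` (default; MAF >= `common_maf` variants enter
#'   the lambda estimate) or `"all"`.
#' @param common_maf MAF threshold used when `lambda_on = "common"`.
#' @return data.frame with variant_id, allele counts, or_, ci_low, ci_high,
#'   chi2, p_raw, p_gc, p_fdr, plus the `lambda_` estimate as an attribute.
#' @export
assoc_scan <- function(G, samples, lambda_on = c("common", "all"),
                       common_maf = 0.05) {
  lambda_on <- match.arg(lambda_on)
  is_case <- samples$status == "case"
  Gc <- G[is_case, , drop = FALSE]
  Gk <- G[!is_case, , drop = FALSE]
  # vectorized allele-count tables across all variants
  a <- colSums(Gc, na.rm = TRUE)
  b <- 2 * colSums(!is.na(Gc)) - a
  c_ <- colSums(Gk, na.rm = TRUE)
  d <- 2 * colSums(!is.na(Gk)) - c_
  n <- a + b + c_ + d
  untestable <- (a + b) == 0 | (c_ + d) == 0 | (a + c_) == 0 | (b + d) == 0
  chi2 <- ifelse(untestable, NA_real_,
                 n * (a * d - b * c_)^2 /
                   ((a + b) * (c_ + d) * (a + c_) * (b + d)))
  p_raw <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  ah <- a + 0.5 * zero; bh <- b + 0.5 * zero
  ch <- c_ + 0.5 * zero; dh <- d + 0.5 * zero
  or_ <- ifelse(untestable, NA_real_, ah * dh / (bh * ch))
  se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  out <- data.frame(
    variant_id = colnames(G),
    case_alt = a, case_ref = b, ctrl_alt = c_, ctrl_ref = d,
    or_ = or_,
    ci_low = exp(log(or_) - stats::qnorm(0.975) * se),
    ci_high = exp(log(or_) + stats::qnorm(0.975) * se),
    chi2 = chi2, p_raw = p_raw, untestable = untestable,
    stringsAsFactors = FALSE, row.names = NULL
  )
  alt_freq <- (out$case_alt + out$ctrl_alt) /
    pmax(1, out$case_alt + out$case_ref + out$ctrl_alt + out$ctrl_ref)
  maf <- pmin(alt_freq, 1 - alt_freq)
  in_lambda <- !out$untestable &
    if (lambda_on == "common") maf >= common_maf else TRUE
  gc <- genomic_control(out$chi2[in_lambda])
  corr <- apply_genomic_control(out$chi2, gc$lambda_)
  out$chi2_gc <- corr$chi2_gc
  out$p_gc <- corr$p_gc
  out$p_fdr <- bh_fdr(out$p_gc)
  attr(out, "lambda_") <- gc$lambda_
  out
}

#' Stratified CMH scan across ethnic (or other) strata
#'
#' Per variant, builds one case/control allele-count table per stratum and
#' combines them with [cmh_test()].
#'
#' @param G samples x variants 0/1/2 matrix.
#' @param samples sample sheet (needs `status` and the stratum column).
#' @param stratum_col column of `samples` defining strata (default
#'   `"stratum"`).
#' @return data.frame: variant_id, or_mh, chi2_cmh, p, untestable.
#' @export
cmh_scan <- function(G, samples, stratum_col = "stratum") {
  strata <- unique(samples[[stratum_col]])
  is_case <- samples$status == "case"
  res <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    tabs <- lapply(strata, function(s) {
      sel <- samples[[stratum_col]] == s
      allele_table(g[sel], is_case[sel])
    })
    # untestable when every stratum is monomorphic
    poly <- vapply(tabs, function(v) (v[1] + v[3]) > 0 && (v[2] + v[4]) > 0, TRUE)
    if (!any(poly)) {
      return(data.frame(variant_id = colnames(G)[j], or_mh = NA_real_,
                        chi2_cmh = NA_real_, p = NA_real_, untestable = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- cmh_test(tabs)
    data.frame(variant_id = colnames(G)[j], or_mh = r$or_mh,
               chi2_cmh = r$chi2_cmh, p = r$p, untestable = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Conditional association scan on a peak variant
#'
#' Tests each remaining variant by CMH with strata defined by the peak
#' variant's genotype classes (0/1/2): association that is entirely explained
#' by the peak disappears, association independent of the peak survives.
#'
#' @param G samples x variants 0/1/2 matrix.
#' @param samples sample sheet (needs `status`).
#' @param peak_variant column name of the conditioning variant.
#' @return data.frame as in [cmh_scan()], excluding the peak itself; variants
#'   monomorphic within every peak-genotype stratum are flagged untestable.
#' @export
conditional_scan <- function(G, samples, peak_variant) {
  if (!peak_variant %in% colnames(G))
    stop_arg("peak variant '", peak_variant, "' not in genotype matrix")
  peak <- G[, peak_variant]
  classes <- sort(unique(peak[!is.na(peak)]))
  if (length(classes) < 2L)
    stop_arg("peak variant '", peak_variant, "' is monomorphic")
  samples2 <- samples
  samples2$.peak_class <- as.character(peak)
  keep <- !is.na(peak)
  rest <- setdiff(colnames(G), peak_variant)
  cmh_scan(G[keep, rest, drop = FALSE], samples2[keep, , drop = FALSE],
           stratum_col = ".peak_class")
}
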