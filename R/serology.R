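#' Control-channel normalization of an autoantigen array
#'
#' Divides each sample's antigen net fluorescence intensities (NFI) by its
#' anti-IgG/IgM control-channel value (the reserved `__control__` row), then
#' rescales by the cohort median control so typical intensities keep their
#' original magnitude.  Samples with a zero control channel are excluded
#' with a warning.
#'
#' @param S antigens x samples matrix including a `__control__` row.
#' @return normalized antigens x samples matrix (control row removed).
#' @export
normalize_nfi <- function(S) {
  if (!"__control__" %in% rownames(S))
    stop_arg("matrix must contain a `__control__` row")
  ctrl <- S["__control__", ]
  A <- S[setdiff(rownames(S), "__control__"), , drop = FALSE]
  if (any(A < 0)) stop_arg("intensities must be >= 0")
  bad <- ctrl <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " sample(s) with zero control channel")
    A <- A[, !bad, drop = FALSE]
    ctrl <- ctrl[!bad]
  }
  sweep(A, 2L, ctrl / stats::median(ctrl), `/`)
}

#' Genotype-group antigen enrichment
#'
#' Per antigen: the fold of group means (risk over comparison group, with a
#' pseudo-floor), a Welch t test on log-scale values, and a flag for folds
#' above the threshold.  Also reports the per-sample average-NFI group
#' comparison (the "average normalized autoantibody level" statistic).
#'
#' @param S_norm normalized antigens x samples matrix (see
#'   [normalize_nfi()]).
#' @param groups character/factor per sample; levels compared are
#'   `risk_level` vs `other_level`.
#' @param risk_level,other_level group labels (defaults `"risk"`,
#'   `"protective"`).
#' @param fold_threshold enrichment flag threshold (default 5).
#' @param pseudo_floor added before log and division (default 1).
#' @param center `"mean"` (default) or `"median"` group summary for folds.
#' @return list with `antigens` (antigen, fold, p, flagged) and
#'   `sample_means` (per-sample mean NFI comparison: mean_risk, mean_other,
#'   p).
#' @export
group_enrichment <- function(S_norm, groups, risk_level = "risk",
                             other_level = "protective",
                             fold_threshold = 5, pseudo_floor = 1,
                             center = c("mean", "median")) {
  center <- match.arg(center)
  gi <- groups == risk_level
  go <- groups == other_level
  if (sum(gi) < 2L || sum(go) < 2L)
    stop_arg("need >= 2 samples in each compared group")
  summ <- if (center == "mean") rowMeans else
    function(M) apply(M, 1L, stats::median)
  fr <- summ(S_norm[, gi, drop = FALSE])
  fo <- summ(S_norm[, go, drop = FALSE])
  fold <- (fr + pseudo_floor) / (fo + pseudo_floor)
  Lr <- log(S_norm[, gi, drop = FALSE] + pseudo_floor)
  Lo <- log(S_norm[, go, drop = FALSE] + pseudo_floor)
  safe_welch_p <- function(x, y) {
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
      return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    stats::t.test(x, y)$p.value
  }
  p <- vapply(seq_len(nrow(S_norm)),
              function(i) safe_welch_p(Lr[i, ], Lo[i, ]), numeric(1))
  antigens <- data.frame(antigen = rownames(S_norm), fold = fold,
                         p = p, flagged = fold > fold_threshold,
                         stringsAsFactors = FALSE, row.names = NULL)
  mr <- colMeans(S_norm[, gi, drop = FALSE])
  mo <- colMeans(S_norm[, go, drop = FALSE])
  p_means <- safe_welch_p(log(mr + pseudo_floor), log(mo + pseudo_floor))
  list(antigens = antigens,
       sample_means = list(mean_risk = mean(mr), mean_other = mean(mo),
                           p = p_means))
}

#' Antigen clustering order
#'
#' Average-linkage hierarchical clustering on correlation distance of the
#' normalized antigen profiles; returns the dendrogram leaf order (no
#' heatmap rendering).
#'
#' @param S_norm normalized antigens x samples matrix (>= 3 antigens).
#' @return character vector of antigen names in dendrogram order.
#' @export
antigen_cluster_order <- function(S_norm) {
  if (nrow(S_norm) < 3L) stop_arg("need >= 3 antigens")
  d <- stats::as.dist(1 - stats::cor(t(S_norm)))
  hc <- stats::hclust(d, method = "average")
  rownames(S_norm)[hc$order]
}
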