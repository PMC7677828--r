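#' Sample quality filter
#'
#' Retains samples with call rate and mean sequencing depth at or above the
#' thresholds; exclusion thresholds are read as strict ("< 85%", "< 25X"
#' excluded), so the boundary values are retained.
#'
#' @param samples data.frame with at least `sample_id`, `call_rate`,
#'   `mean_depth`.
#' @param min_call_rate minimum genotype call rate retained (default 0.85).
#' @param min_depth minimum mean fold coverage retained (default 25).
#' @return list with `retained` and `excluded` data.frames; `excluded` gains
#'   a `reason` column (`"call_rate"`, `"depth"` or `"call_rate;depth"`).
#' @export
filter_samples <- function(samples, min_call_rate = 0.85, min_depth = 25) {
  if (min_call_rate < 0 || min_call_rate > 1)
    stop_arg("`min_call_rate` must be in [0,1]")
  if (min_depth < 0) stop_arg("`min_depth` must be >= 0")
  if (nrow(samples) == 0L) {
    return(list(retained = samples,
                excluded = cbind(samples, reason = character(0))))
  }
  bad_cr <- samples$call_rate < min_call_rate
  bad_dp <- samples$mean_depth < min_depth
  reason <- rep(NA_character_, nrow(samples))
  reason[bad_cr] <- "call_rate"
  reason[bad_dp] <- ifelse(bad_cr[bad_dp], "call_rate;depth", "depth")
  keep <- !(bad_cr | bad_dp)
  excluded <- samples[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = samples[keep, , drop = FALSE], excluded = excluded)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' `method = "chi2"` is the Pearson 1-df goodness-of-fit statistic against
#' expected Hardy-Weinberg genotype counts.  `method = "exact"` enumerates
#' every heterozygote count compatible with the observed allele counts
#' (Levene-Haldane conditional distribution) and sums the probability of all
#' tables whose probability does not exceed the observed one (no mid-p).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (any allele labelling; the test is
#'   symmetric in the two homozygote classes).
#' @param method `"exact"` (default) or `"chi2"`.
#' @return list with `p` and, for chi2, `chi2`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chi2")) {
  method <- match.arg(method)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop_arg("genotype counts must be >= 0")
  n <- sum(counts)
  if (n == 0L) stop_arg("total genotype count is zero")
  if (method == "chi2") {
    p <- (2 * n_AA + n_Aa) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(list(chi2 = 0, p = 1))  # monomorphic
    chi2 <- sum((counts - e)^2 / e)
    return(list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)))
  }
  # exact: enumerate heterozygote counts with the parity of the minor-allele
  # count, conditional on allele counts
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  list(p = min(1, sum(pr[pr <= obs * (1 + 1e-12)])))
}

#' Per-variant statistics
#'
#' Computes, for every variant column of a genotype matrix: alternate and
#' minor allele frequencies over non-missing alleles (MAF folded to <= 0.5),
#' call rate, an HWE p-value on control genotypes, and a frequency class
#' (`common` iff MAF >= `common_maf`).  Variants with no called genotypes are
#' flagged `all_missing` and should be excluded downstream.
#'
#' @param G samples x variants matrix of 0/1/2 codes with NA for missing.
#' @param samples sample sheet aligned to `rownames(G)` (needs `sample_id`,
#'   `status`, `stratum`).
#' @param common_maf MAF threshold for the common class (default 0.05).
#' @param hwe_method passed to [hwe_test()].
#' @param hwe_per_stratum if TRUE (default) the HWE p is the minimum over
#'   per-stratum control tests; FALSE pools all controls.
#' @param annotation_flags optional data.frame of logical columns (rownames =
#'   variant ids) carried through to the output.
#' @return data.frame, one row per variant: variant_id, position (if the
#'   matrix has a `position` attribute), alt_freq, maf, call_rate,
#'   hwe_p_controls, freq_class, all_missing, plus any annotation columns.
#' @export
variant_stats <- function(G, samples, common_maf = 0.05,
                          hwe_method = "exact", hwe_per_stratum = TRUE,
                          annotation_flags = NULL) {
  stopifnot(nrow(G) == nrow(samples))
  is_ctrl <- samples$status == "control"
  strata <- unique(samples$stratum)
  res <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    called <- !is.na(g)
    n2 <- 2 * sum(called)
    alt <- if (n2 > 0) sum(g[called]) / n2 else NA_real_
    maf <- if (is.na(alt)) NA_real_ else min(alt, 1 - alt)
    hwe_p <- NA_real_
    gc <- g[is_ctrl & called]
    if (length(gc) > 0) {
      if (hwe_per_stratum) {
        ps <- vapply(strata, function(s) {
          gs <- g[is_ctrl & called & samples$stratum == s]
          if (length(gs) == 0) return(NA_real_)
          hwe_test(sum(gs == 0L), sum(gs == 1L), sum(gs == 2L),
                   method = hwe_method)$p
        }, numeric(1))
        hwe_p <- if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
      } else {
        hwe_p <- hwe_test(sum(gc == 0L), sum(gc == 1L), sum(gc == 2L),
                          method = hwe_method)$p
      }
    }
    data.frame(
      variant_id = colnames(G)[j],
      alt_freq = alt, maf = maf,
      call_rate = mean(called),
      hwe_p_controls = hwe_p,
      freq_class = if (is.na(maf)) NA_character_
                   else if (maf >= common_maf) "common" else "low_frequency",
      all_missing = n2 == 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  pos <- attr(G, "position")
  if (!is.null(pos)) out$position <- pos
  if (!is.null(annotation_flags)) {
    out <- cbind(out, annotation_flags[out$variant_id, , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Variant filter by QC thresholds
#'
#' Excludes all-missing variants, variants below a call-rate floor, and
#' variants out of Hardy-Weinberg equilibrium in controls
#' (`hwe_p_controls < hwe_alpha`).
#'
#' @param stats output of [variant_stats()].
#' @param min_call_rate minimum variant call rate (default 0.85).
#' @param hwe_alpha HWE exclusion level in controls (default 0.001).
#' @return list with `retained` and `excluded` (with `reason`).
#' @export
filter_variants <- function(stats, min_call_rate = 0.85, hwe_alpha = 0.001) {
  reason <- rep(NA_character_, nrow(stats))
  reason[stats$all_missing] <- "all_missing"
  low_cr <- !stats$all_missing & stats$call_rate < min_call_rate
  reason[low_cr] <- "call_rate"
  hwe_bad <- is.na(reason) & !is.na(stats$hwe_p_controls) &
    stats$hwe_p_controls < hwe_alpha
  reason[hwe_bad] <- "hwe"
  keep <- is.na(reason)
  excluded <- stats[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = stats[keep, , drop = FALSE], excluded = excluded)
}

#' Variant density and annotation summary
#'
#' Summarizes a variant table over a genomic region: overall and common
#' variants per kb (rounded to 1 decimal), counts per frequency class, and
#' the fraction of variants carrying each logical annotation flag, reported
#' as nearest-integer percent.
#'
#' @param stats data.frame with `freq_class` and optional logical annotation
#'   columns.
#' @param region_kb region length in kb (> 0).
#' @param flag_cols names of logical annotation columns to summarize
#'   (default: every logical column).
#' @return list with `n_total`, `n_common`, `n_low_frequency`,
#'   `density_per_kb`, `common_density_per_kb`, `flag_percent` (named
#'   integer vector).
#' @export
density_summary <- function(stats, region_kb, flag_cols = NULL) {
  if (region_kb <= 0) stop_arg("`region_kb` must be > 0")
  n <- nrow(stats)
  n_common <- sum(stats$freq_class == "common", na.rm = TRUE)
  if (is.null(flag_cols))
    flag_cols <- names(stats)[vapply(stats, is.logical, TRUE) &
                                names(stats) != "all_missing"]
  flag_pct <- if (n == 0) stats::setNames(integer(0), character(0)) else
    vapply(flag_cols, function(cn) as.integer(round(100 * sum(stats[[cn]], na.rm = TRUE) / n)),
           integer(1))
  list(
    n_total = n,
    n_common = n_common,
    n_low_frequency = sum(stats$freq_class == "low_frequency", na.rm = TRUE),
    density_per_kb = round(n / region_kb, 1),
    common_density_per_kb = round(n_common / region_kb, 2),
    flag_percent = flag_pct
  )
}
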