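#' Per-stratum haplotype frequencies by case/control group
#'
#' Runs [em_haplotype_frequencies()] separately on each stratum x group
#' subset and labels the estimated haplotypes against a panel.
#'
#' @param G samples x tag-sites genotype matrix.
#' @param samples sample sheet aligned to rows (needs `status`, `stratum`).
#' @param panel `haplotype_panel` used for labelling.
#' @param ... passed to [em_haplotype_frequencies()].
#' @return data.frame: stratum, status, label, haplotype, freq,
#'   expected_count.
#' @export
stratified_haplotype_frequencies <- function(G, samples, panel, ...) {
  out <- list()
  for (st in unique(samples$stratum)) {
    for (grp in unique(samples$status)) {
      sel <- samples$stratum == st & samples$status == grp
      if (!any(sel)) next
      tab <- em_haplotype_frequencies(G[sel, , drop = FALSE], ...)
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, status = grp,
        label = label_haplotypes(tab$haplotype, panel),
        haplotype = tab$haplotype, freq = tab$freq,
        expected_count = tab$expected_count,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Haplotype case-control association across strata
#'
#' Each haplotype label is tested as a 2x2 table (this haplotype vs all
#' others, expected chromosome counts rounded to the nearest integer) per
#' stratum, and strata are combined with [cmh_test()].  A label absent from
#' one group of a stratum contributes a zero cell (handled by the CMH
#' arithmetic; the per-stratum allelic OR uses the +0.5 correction).
#'
#' @param freq_table output of [stratified_haplotype_frequencies()].
#' @param round_counts round expected counts to integers (default TRUE,
#'   Haploview-style); FALSE uses the fractional counts directly.
#' @return data.frame, one row per haplotype label: label, or_mh, chi2_cmh,
#'   p, n_strata; per-stratum tables in the `tables` attribute.
#' @export
haplotype_assoc <- function(freq_table, round_counts = TRUE) {
  labels <- setdiff(unique(freq_table$label), NA)
  strata <- unique(freq_table$stratum)
  all_tables <- list()
  rows <- lapply(labels, function(lab) {
    tabs <- lapply(strata, function(st) {
      cnt <- function(grp, this) {
        sel <- freq_table$stratum == st & freq_table$status == grp &
          (if (this) freq_table$label == lab else freq_table$label != lab)
        x <- sum(freq_table$expected_count[sel])
        if (round_counts) round(x) else x
      }
      c(cnt("case", TRUE), cnt("case", FALSE),
        cnt("control", TRUE), cnt("control", FALSE))
    })
    all_tables[[lab]] <<- tabs
    r <- cmh_test(tabs)
    data.frame(label = lab, or_mh = r$or_mh, chi2_cmh = r$chi2_cmh,
               p = r$p, n_strata = r$n_strata, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- all_tables
  out
}

#' Diplotype assignments from EM phase posteriors
#'
#' Maximum-posterior phase per sample, labelled against a panel, with the
#' additive dose score (HAP1 = 0, HAP2 = 1, HAP3 = 2 per copy, summed;
#' `NA` when either copy is labelled OTHER).
#'
#' @param G samples x tag-sites genotype matrix.
#' @param samples sample sheet aligned to rows.
#' @param panel `haplotype_panel`.
#' @param ... passed to [em_haplotype_frequencies()].
#' @return data.frame: sample_id, status, stratum, hap_a, hap_b (labels),
#'   posterior, score.
#' @export
assign_diplotypes <- function(G, samples, panel, ...) {
  tab <- em_haplotype_frequencies(G, ...)
  asn <- attr(tab, "assignments")
  score_of <- c(HAP1 = 0L, HAP2 = 1L, HAP3 = 2L)
  la <- label_haplotypes(asn$hap_a, panel)
  lb <- label_haplotypes(asn$hap_b, panel)
  # excluded samples (too much missingness) are dropped from the output
  idx <- match(asn$sample, samples$sample_id)
  data.frame(
    sample_id = asn$sample,
    status = samples$status[idx],
    stratum = samples$stratum[idx],
    hap_a = pmin(la, lb), hap_b = pmax(la, lb),
    posterior = asn$posterior,
    score = unname(score_of[la] + score_of[lb]),
    stringsAsFactors = FALSE
  )
}

#' Diplotype dose-effect association
#'
#' Tests each diplotype's 2x2 odds ratio against a reference diplotype
#' (default the protective homozygote HAP1/HAP1) and reports a monotone
#' trend over the additive dose score via linear regression of case status
#' on score.
#'
#' @param assignments output of [assign_diplotypes()] (or any data.frame
#'   with `status`, `hap_a`, `hap_b`, `score`).
#' @param reference length-2 character reference diplotype (default
#'   `c("HAP1", "HAP1")`).
#' @return list with `per_diplotype` (diplotype, n_case, n_control, or_,
#'   ci_low, ci_high, p) and `trend` (slope, t, p, n; slope > 0 means risk
#'   increases with dose).
#' @export
diplotype_dose <- function(assignments, reference = c("HAP1", "HAP1")) {
  ref_key <- paste(sort(reference), collapse = "/")
  key <- paste(assignments$hap_a, assignments$hap_b, sep = "/")
  is_case <- assignments$status == "case"
  n_case_ref <- sum(is_case & key == ref_key)
  n_ctrl_ref <- sum(!is_case & key == ref_key)
  if (n_case_ref == 0 || n_ctrl_ref == 0)
    stop_arg("reference diplotype ", ref_key,
             " must be present in both cases and controls")
  others <- setdiff(unique(key), ref_key)
  per <- lapply(others, function(k) {
    a <- sum(is_case & key == k); c <- sum(!is_case & key == k)
    r <- allelic_test(a, n_case_ref, c, n_ctrl_ref)
    data.frame(diplotype = k, n_case = a, n_control = c,
               or_ = r$or_, ci_low = r$ci95[1], ci_high = r$ci95[2],
               p = r$p_raw, stringsAsFactors = FALSE)
  })
  per_diplotype <- if (length(per)) do.call(rbind, per) else
    data.frame(diplotype = character(0), n_case = integer(0),
               n_control = integer(0), or_ = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0))
  ok <- !is.na(assignments$score)
  trend <- if (length(unique(assignments$score[ok])) < 2) {
    list(slope = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok))
  } else {
    fit <- stats::lm(as.integer(is_case)[ok] ~ assignments$score[ok])
    cf <- summary(fit)$coefficients
    list(slope = cf[2, 1], t = cf[2, 3], p = cf[2, 4], n = sum(ok))
  }
  list(per_diplotype = per_diplotype, trend = trend)
}
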