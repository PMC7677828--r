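#' Default three-haplotype regulatory panel
#'
#' Builds the nested three-haplotype panel used throughout the package: a
#' protective all-reference haplotype (HAP1), a risk all-alternate haplotype
#' (HAP3) differing from HAP1 at every site, and an intermediate haplotype
#' (HAP2) carrying the alternate allele at the first `n_hap2_diffs` sites.
#' With the defaults (19 sites, 15 differences) the pairwise Hamming
#' distances are HAP1-HAP3 = 19, HAP1-HAP2 = 15 and HAP2-HAP3 = 4, matching
#' the divergence structure of a multi-ethnic regulatory locus in which the
#' protective and risk alleles differ at all tagged sites.
#'
#' Default stratum frequencies describe three ancestry strata (EA, AA, AS):
#' the protective haplotype is common in EA and rarer elsewhere, while the
#' risk haplotype is low-frequency (~0.10-0.15) everywhere.
#'
#' @param n_sites number of SNP positions in the panel.
#' @param n_hap2_diffs number of leading sites at which HAP2 carries the
#'   alternate allele; must satisfy `0 < n_hap2_diffs <= n_sites`.
#' @param freqs optional named list `stratum -> named numeric` of haplotype
#'   frequencies; each vector must be named by haplotype label and sum to 1.
#' @return an object of class `haplotype_panel`: a list with `n_sites`,
#'   `haplotypes` (named list of 0/1 integer vectors) and `freqs`.
#' @examples
#' p <- make_default_panel(19, 15)
#' sum(p$haplotypes$HAP1 != p$haplotypes$HAP3)  # 19
#' @export
make_default_panel <- function(n_sites = 19L, n_hap2_diffs = 15L, freqs = NULL) {
  n_sites <- as.integer(n_sites)
  n_hap2_diffs <- as.integer(n_hap2_diffs)
  if (is.na(n_sites) || n_sites < 1L)
    stop_arg("`n_sites` must be a positive integer")
  if (is.na(n_hap2_diffs) || n_hap2_diffs < 1L || n_hap2_diffs > n_sites)
    stop_arg("`n_hap2_diffs` must be in 1..n_sites")
  haps <- list(
    HAP1 = rep(0L, n_sites),
    HAP2 = c(rep(1L, n_hap2_diffs), rep(0L, n_sites - n_hap2_diffs)),
    HAP3 = rep(1L, n_sites)
  )
  if (is.null(freqs)) {
    freqs <- list(
      EA = c(HAP1 = 0.55, HAP2 = 0.35, HAP3 = 0.10),
      AA = c(HAP1 = 0.15, HAP2 = 0.70, HAP3 = 0.15),
      AS = c(HAP1 = 0.20, HAP2 = 0.65, HAP3 = 0.15)
    )
  }
  panel <- structure(
    list(n_sites = n_sites, haplotypes = haps, freqs = freqs),
    class = "haplotype_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  lens <- vapply(panel$haplotypes, length, 1L)
  if (any(lens != panel$n_sites))
    stop_arg("all haplotype bit-vectors must have length n_sites")
  if (anyDuplicated(names(panel$haplotypes)))
    stop_arg("haplotype labels must be unique")
  for (s in names(panel$freqs)) {
    f <- panel$freqs[[s]]
    if (!all(names(f) %in% names(panel$haplotypes)))
      stop_arg("stratum '", s, "' names an unknown haplotype")
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop_arg("stratum '", s, "' frequencies must be non-negative and sum to 1")
  }
  invisible(panel)
}

#' Restrict a panel to a subset of sites
#'
#' @param panel a `haplotype_panel`.
#' @param idx site indices to keep (in order).
#' @return a `haplotype_panel` over the selected sites (frequencies carried
#'   over unchanged).
#' @export
subset_panel <- function(panel, idx) {
  p <- panel
  p$n_sites <- length(idx)
  p$haplotypes <- lapply(panel$haplotypes, function(h) h[idx])
  validate_panel(p)
}

#' Cohort specification for the case-control sampler
#'
#' @param strata data.frame with columns `name`, `n_cases`, `n_controls`.
#'   Defaults mirror a three-cohort design: EA 773/576, AA 182/181,
#'   AS 160/160.
#' @param haplotype_or named numeric of per-haplotype odds ratios relative to
#'   the non-listed (reference-class) haplotypes; defaults encode a risk
#'   haplotype at OR 1.5 and a protective haplotype at OR 0.7.
#' @param seed integer seed; all randomness in the sampler flows from it.
#' @param mutation_rate per-site, per-drawn-haplotype allele-flip probability
#'   (default 0), used to create rare recombinant-like network intermediates.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(strata = NULL,
                        haplotype_or = c(HAP3 = 1.5, HAP1 = 0.7),
                        seed = 1L,
                        mutation_rate = 0) {
  if (is.null(strata)) {
    strata <- data.frame(
      name = c("EA", "AA", "AS"),
      n_cases = c(773L, 182L, 160L),
      n_controls = c(576L, 181L, 160L),
      stringsAsFactors = FALSE
    )
  }
  if (any(strata$n_cases <= 0L) || any(strata$n_controls <= 0L))
    stop_arg("stratum sample counts must be positive")
  if (any(haplotype_or <= 0)) stop_arg("odds ratios must be positive")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_arg("`mutation_rate` must be in [0,1]")
  structure(list(strata = strata, haplotype_or = haplotype_or,
                 seed = as.integer(seed), mutation_rate = mutation_rate),
            class = "cohort_spec")
}

#' Case haplotype frequencies implied by control frequencies and odds ratios
#'
#' Retrospective sampling transform: each haplotype with a stated odds ratio
#' gets the carrier-odds transform `f' = f*OR / (f*OR + 1 - f)`, which makes
#' its carrier-chromosome odds ratio between cases and controls exactly `OR`
#' by construction.  Haplotypes without a stated OR (the reference class)
#' share the residual probability mass in proportion to their control
#' frequencies.
#'
#' @param control_freqs named numeric control haplotype frequencies (sum 1).
#' @param haplotype_or named numeric odds ratios for a subset of haplotypes.
#' @return named numeric case haplotype frequencies.
#' @export
case_frequencies <- function(control_freqs, haplotype_or) {
  if (abs(sum(control_freqs) - 1) > 1e-9)
    stop_arg("control frequencies must sum to 1")
  bad <- setdiff(names(haplotype_or), names(control_freqs))
  if (length(bad))
    stop_arg("odds ratios name unknown haplotypes: ", paste(bad, collapse = ", "))
  out <- control_freqs
  eff <- names(haplotype_or)
  for (h in eff) {
    f <- control_freqs[[h]]
    if (f >= 1 && haplotype_or[[h]] != 1)
      warning("haplotype '", h, "' carries all probability mass; OR unattainable")
    out[[h]] <- f * haplotype_or[[h]] / (f * haplotype_or[[h]] + 1 - f)
  }
  ref <- setdiff(names(control_freqs), eff)
  resid <- 1 - sum(out[eff])
  if (resid < 0)
    stop_arg("odds-ratio transform leaves no mass for reference haplotypes")
  if (length(ref)) {
    w <- control_freqs[ref]
    out[ref] <- if (sum(w) > 0) resid * w / sum(w) else resid / length(ref)
  }
  out
}

#' Simulate diploid genotypes for a stratified case-control cohort
#'
#' Controls draw two haplotypes per individual from the stratum control
#' frequencies; cases draw from the case frequencies given by
#' [case_frequencies()].  Genotype codes are 0/1/2 alternate-allele counts,
#' always the exact sum of the two drawn haplotypes' alleles (plus optional
#' mutation flips applied to the drawn haplotypes before summing).
#'
#' @param panel a `haplotype_panel`.
#' @param spec a `cohort_spec`; every stratum name must have frequencies in
#'   the panel.
#' @return list with `genotypes` (samples x sites integer matrix of 0/1/2),
#'   `samples` (sample sheet: sample_id, status, stratum, sex, call_rate,
#'   mean_depth) and `truth` (per-sample drawn haplotype labels, allele
#'   strings and diplotype score: HAP1 = 0, HAP2 = 1, HAP3 = 2 per copy).
#' @export
simulate_genotypes <- function(panel, spec) {
  validate_panel(panel)
  set.seed(spec$seed)
  hap_names <- names(panel$haplotypes)
  hap_mat <- do.call(rbind, panel$haplotypes)      # labels x sites
  score_of <- stats::setNames(match(hap_names, c("HAP1", "HAP2", "HAP3")) - 1L,
                              hap_names)
  rows <- list()
  for (i in seq_len(nrow(spec$strata))) {
    st <- spec$strata$name[i]
    f_ctrl <- panel$freqs[[st]]
    if (is.null(f_ctrl)) stop_arg("panel has no frequencies for stratum '", st, "'")
    f_ctrl <- f_ctrl[f_ctrl > 0]
    f_case <- case_frequencies(f_ctrl, spec$haplotype_or[names(spec$haplotype_or) %in% names(f_ctrl)])
    for (grp in c("control", "case")) {
      n <- if (grp == "case") spec$strata$n_cases[i] else spec$strata$n_controls[i]
      f <- if (grp == "case") f_case else f_ctrl
      draws <- matrix(sample(names(f), 2L * n, replace = TRUE, prob = f),
                      ncol = 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, status = grp, hap_a = draws[, 1L], hap_b = draws[, 2L],
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  n_tot <- nrow(truth)
  truth$sample_id <- sprintf("S%04d", seq_len(n_tot))
  A <- hap_mat[truth$hap_a, , drop = FALSE]
  B <- hap_mat[truth$hap_b, , drop = FALSE]
  if (spec$mutation_rate > 0) {
    flipA <- matrix(stats::runif(length(A)) < spec$mutation_rate, nrow(A))
    flipB <- matrix(stats::runif(length(B)) < spec$mutation_rate, nrow(B))
    A <- abs(A - flipA); B <- abs(B - flipB)
    storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  }
  G <- A + B
  rownames(G) <- truth$sample_id
  colnames(G) <- sprintf("snp%02d", seq_len(panel$n_sites))
  truth$allele_a <- apply(A, 1L, hap_to_string)
  truth$allele_b <- apply(B, 1L, hap_to_string)
  truth$score <- unname(score_of[truth$hap_a] + score_of[truth$hap_b])
  samples <- data.frame(
    sample_id = truth$sample_id,
    status = truth$status,
    stratum = truth$stratum,
    sex = sample(c("F", "M"), n_tot, replace = TRUE, prob = c(0.9, 0.1)),
    call_rate = pmin(1, stats::rbeta(n_tot, 80, 2)),
    mean_depth = stats::rgamma(n_tot, shape = 40, scale = 153.2 / 40),
    stringsAsFactors = FALSE
  )
  list(genotypes = G,
       samples = samples,
       truth = truth[, c("sample_id", "status", "stratum",
                         "hap_a", "hap_b", "allele_a", "allele_b", "score")])
}

#' Simulate an RPKM expression matrix with a cis-eQTL target gene
#'
#' The target gene (row `"TARGET"`) follows an additive dose model:
#' `baseline - effect_per_score * score + N(0, noise_sd)`, so with the
#' defaults (baseline 10, effect 1) risk-homozygote carriers (score 4) sit
#' 40% below reference homozygotes.  `n_de_genes` genes (rows `DE...`) are
#' shifted multiplicatively by `de_fold` in case samples; all remaining genes
#' form a reference-stable pool with a common mean and variance.
#'
#' @param truth truth record from [simulate_genotypes()] (needs `sample_id`,
#'   `status`, `score`).
#' @param n_genes total gene count (default 1000).
#' @param baseline target-gene mean RPKM in score-0 individuals.
#' @param effect_per_score RPKM decrement per unit diplotype score.
#' @param noise_sd residual SD (RPKM units) for every gene.
#' @param n_de_genes number of genes truly DE between cases and controls.
#' @param de_fold true case/control fold change for DE genes.
#' @param stable_mean mean RPKM of the reference-stable pool.
#' @param seed integer seed.
#' @return genes x samples numeric matrix (RPKM); negative values are
#'   clipped at 0 with a warning.
#' @export
simulate_expression <- function(truth, n_genes = 1000L, baseline = 10,
                                effect_per_score = 1, noise_sd = 1,
                                n_de_genes = 20L, de_fold = 2,
                                stable_mean = 10, seed = 1L) {
  if (noise_sd < 0) stop_arg("`noise_sd` must be >= 0")
  if (baseline <= 0) stop_arg("`baseline` must be > 0")
  if (de_fold <= 0) stop_arg("`de_fold` must be > 0")
  if (n_de_genes >= n_genes) stop_arg("`n_de_genes` must be < `n_genes`")
  set.seed(seed)
  n <- nrow(truth)
  M <- matrix(stats::rnorm(n_genes * n, mean = stable_mean, sd = noise_sd),
              nrow = n_genes, ncol = n)
  rownames(M) <- c("TARGET",
                   if (n_de_genes > 0) sprintf("DE%03d", seq_len(n_de_genes)),
                   sprintf("G%04d", seq_len(n_genes - 1L - n_de_genes)))
  colnames(M) <- truth$sample_id
  M["TARGET", ] <- baseline - effect_per_score * truth$score +
    stats::rnorm(n, 0, noise_sd)
  if (n_de_genes > 0) {
    is_case <- truth$status == "case"
    de_rows <- sprintf("DE%03d", seq_len(n_de_genes))
    M[de_rows, is_case] <- stats::rnorm(sum(is_case) * n_de_genes,
                                        mean = stable_mean * de_fold,
                                        sd = noise_sd)
  }
  if (any(M < 0)) {
    warning(sum(M < 0), " negative simulated expression values clipped at 0")
    M[M < 0] <- 0
  }
  M
}

#' Simulate an autoantigen-array serology matrix
#'
#' Antigen intensities are log-normal background values multiplied by a
#' per-sample array factor (captured by the `__control__` channel, so that
#' control-channel normalization can remove it).  Antigens listed in `shift`
#' are multiplied by their shift factor in samples belonging to the risk
#' diplotype group (`score >= risk_score`).
#'
#' @param truth truth record from [simulate_genotypes()].
#' @param antigens character vector of antigen names.
#' @param shift named numeric of per-antigen multiplicative shifts in the
#'   risk group (default: 6-fold for `"Sm"` if present).
#' @param risk_score minimum diplotype score defining the risk group
#'   (default 4, i.e. risk homozygotes).
#' @param meanlog,sdlog background log-normal parameters.
#' @param seed integer seed.
#' @return antigens x samples matrix with an extra `__control__` row holding
#'   the per-sample control-channel intensity.
#' @export
simulate_serology <- function(truth,
                              antigens = c("Sm", "SmD", "U1-snRNP-BB",
                                           "thyroglobulin",
                                           sprintf("Ag%02d", 1:16)),
                              shift = c(Sm = 6),
                              risk_score = 4L,
                              meanlog = log(100), sdlog = 0.5,
                              seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  k <- length(antigens)
  bad <- setdiff(names(shift), antigens)
  if (length(bad)) stop_arg("shift names unknown antigens: ", paste(bad, collapse = ", "))
  S <- matrix(stats::rlnorm(k * n, meanlog, sdlog), nrow = k,
              dimnames = list(antigens, truth$sample_id))
  risk <- truth$score >= risk_score
  for (ag in names(shift)) S[ag, risk] <- S[ag, risk] * shift[[ag]]
  array_factor <- stats::rlnorm(n, 0, 0.3)
  S <- sweep(S, 2L, array_factor, `*`)
  ctrl <- stats::rlnorm(n, log(50), 0.1) * array_factor
  rbind(S, `__control__` = ctrl)
}
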