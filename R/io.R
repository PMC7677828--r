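#' Write a genotype matrix as VCF 4.2
#'
#' One biallelic SNV record per site on chr5, positions spaced uniformly
#' within a configurable window, GT as unphased `a/b` with `./.` for
#' missing.
#'
#' @param G samples x variants 0/1/2 matrix (NA = missing).
#' @param path output file (plain text `.vcf`).
#' @param chrom chromosome name (default `"5"`).
#' @param positions 1-based positions per variant; default spaces the
#'   variants evenly across `window`.
#' @param window default position window (1-based, inclusive), matching a
#'   102-kb target region.
#' @return invisibly, the positions used.
#' @export
write_genotypes_vcf <- function(G, path, chrom = "5", positions = NULL,
                                window = c(10678000L, 10780000L)) {
  m <- ncol(G)
  if (is.null(positions))
    positions <- as.integer(round(seq(window[1], window[2], length.out = m)))
  gt <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    g <- G[, j]
    calls <- ifelse(is.na(g), "./.", gt[g + 1L])
    paste(c(chrom, positions[j], colnames(G)[j], "A", "G", ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(positions)
}

#' Read genotypes from a VCF and a sample sheet
#'
#' Parses a VCF 4.x with GT calls into a samples x variants 0/1/2 matrix
#' (`./.` becomes NA), ordered by the sample sheet; positions are attached
#' as the `position` attribute.  Multi-allelic records and sheet/VCF sample
#' mismatches are errors.
#'
#' @param vcf_path plain or bgzipped VCF file.
#' @param sample_sheet data.frame with `sample_id` (plus any QC columns), or
#'   a path to a TSV with those columns.
#' @return list with `genotypes` and `samples`.
#' @export
read_genotypes <- function(vcf_path, sample_sheet) {
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  v <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  nalt <- lengths(rr$ALT)
  if (any(nalt != 1L))
    stop_arg("multi-allelic record(s) at position(s): ",
             paste(utils::head(BiocGenerics::start(rr)[nalt != 1L]), collapse = ", "))
  gt <- VariantAnnotation::geno(v)$GT          # variants x samples
  vcf_samples <- colnames(gt)
  missing_in_vcf <- setdiff(sample_sheet$sample_id, vcf_samples)
  missing_in_sheet <- setdiff(vcf_samples, sample_sheet$sample_id)
  if (length(missing_in_vcf) || length(missing_in_sheet))
    stop_arg("sample sheet / VCF mismatch; missing in VCF: ",
             paste(missing_in_vcf, collapse = ","), "; missing in sheet: ",
             paste(missing_in_sheet, collapse = ","))
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  G <- apply(gt, 2L, code)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  G <- t(G)                                    # samples x variants
  colnames(G) <- rownames(gt)
  G <- G[sample_sheet$sample_id, , drop = FALSE]
  attr(G, "position") <- BiocGenerics::start(rr)
  list(genotypes = G, samples = sample_sheet)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold with the stratum design and seed;
#' round-trips through JSON.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for [run_pipeline()].
#' @param min_call_rate,min_depth sample QC thresholds.
#' @param common_maf common-variant MAF threshold.
#' @param hwe_alpha HWE control-exclusion level.
#' @param tag_dprime D' threshold for tag selection.
#' @param de differential-expression thresholds, a [de_config()].
#' @param serology_fold serology enrichment fold threshold.
#' @param region_kb region length for density summaries.
#' @param panel_sites,panel_hap2_diffs synthetic panel geometry.
#' @param strata optional stratum design data.frame (`name`, `n_cases`,
#'   `n_controls`); NULL uses the [cohort_spec()] defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("hapcohort_run_"),
                            min_call_rate = 0.85, min_depth = 25,
                            common_maf = 0.05, hwe_alpha = 0.001,
                            tag_dprime = 0.8, de = de_config(),
                            serology_fold = 5, region_kb = 102,
                            panel_sites = 19L, panel_hap2_diffs = 15L,
                            strata = NULL) {
  if (!is.null(strata)) strata <- as.data.frame(strata)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 min_call_rate = min_call_rate, min_depth = min_depth,
                 common_maf = common_maf, hwe_alpha = hwe_alpha,
                 tag_dprime = tag_dprime, de = de,
                 serology_fold = serology_fold, region_kb = region_kb,
                 panel_sites = as.integer(panel_sites),
                 panel_hap2_diffs = as.integer(panel_hap2_diffs),
                 strata = strata),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$de <- unclass(x$de)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[setdiff(names(x), "de")]
  args$de <- do.call(de_config, as.list(x$de))
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, writes its VCF/TSV inputs, then runs QC, the
#' genomic-control association scan, the stratified CMH scan, haplotype
#' estimation and association, the median-joining network, the diplotype
#' dose analysis, the cis-eQTL trend, the internal-standards DE procedure
#' and the serology enrichment, writing one output file per stage plus a
#' JSON manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return list of stage results (invisibly also written under
#'   `cfg$out_dir`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(name, path) manifest[[name]] <<- basename(path)

  panel <- make_default_panel(cfg$panel_sites, cfg$panel_hap2_diffs)
  sim <- simulate_genotypes(panel, cohort_spec(strata = cfg$strata,
                                               seed = cfg$seed))
  vcf <- file.path(cfg$out_dir, "genotypes.vcf")
  write_genotypes_vcf(sim$genotypes, vcf)
  emit("simulate_vcf", vcf)
  emit("simulate_samples",
       write_tsv(sim$samples, file.path(cfg$out_dir, "samples.tsv")))

  qc <- filter_samples(sim$samples, cfg$min_call_rate, cfg$min_depth)
  keep <- sim$samples$sample_id %in% qc$retained$sample_id
  G <- sim$genotypes[keep, , drop = FALSE]
  samples <- sim$samples[keep, , drop = FALSE]
  truth <- sim$truth[keep, , drop = FALSE]
  vs <- variant_stats(G, samples, common_maf = cfg$common_maf,
                      hwe_method = "chi2")
  vflt <- filter_variants(vs, hwe_alpha = cfg$hwe_alpha)
  excl <- rbind(
    if (nrow(qc$excluded))
      data.frame(id = qc$excluded$sample_id, kind = "sample",
                 reason = qc$excluded$reason) else NULL,
    if (nrow(vflt$excluded))
      data.frame(id = vflt$excluded$variant_id, kind = "variant",
                 reason = vflt$excluded$reason) else NULL
  )
  if (is.null(excl))
    excl <- data.frame(id = character(0), kind = character(0),
                       reason = character(0))
  emit("qc_variants", write_tsv(vs, file.path(cfg$out_dir, "variant_stats.tsv")))
  emit("qc_exclusions", write_tsv(excl, file.path(cfg$out_dir, "exclusions.tsv")))
  G <- G[, vflt$retained$variant_id, drop = FALSE]

  assoc <- assoc_scan(G, samples, common_maf = cfg$common_maf)
  emit("assoc", write_tsv(assoc, file.path(cfg$out_dir, "assoc.tsv")))
  cmh <- cmh_scan(G, samples)
  emit("cmh", write_tsv(cmh, file.path(cfg$out_dir, "cmh.tsv")))

  peak <- assoc$variant_id[which.min(assoc$p_gc)]
  tags <- select_tag_set(G, peak, cfg$tag_dprime)
  emit("tags", write_tsv(tags, file.path(cfg$out_dir, "tags.tsv")))
  G <- G[, tags$variant_id, drop = FALSE]
  site_idx <- match(colnames(G), colnames(sim$genotypes))
  tag_panel <- subset_panel(panel, site_idx)

  freqs <- stratified_haplotype_frequencies(G, samples, tag_panel)
  emit("haplotype_freqs",
       write_tsv(freqs, file.path(cfg$out_dir, "haplotype_freqs.tsv")))
  hassoc <- haplotype_assoc(freqs)
  emit("haplotype_assoc",
       write_tsv(hassoc, file.path(cfg$out_dir, "haplotype_assoc.tsv")))

  counts <- tapply(freqs$expected_count, freqs$haplotype, sum)
  net <- build_mj_network(names(counts), as.numeric(counts))
  case_counts <- tapply(freqs$expected_count[freqs$status == "case"],
                        freqs$haplotype[freqs$status == "case"], sum)
  ctrl_counts <- tapply(freqs$expected_count[freqs$status == "control"],
                        freqs$haplotype[freqs$status == "control"], sum)
  net <- annotate_nodes(net, case_counts, ctrl_counts)
  gml <- file.path(cfg$out_dir, "mj_network.graphml")
  write_mj_network(net, gml, "graphml")
  emit("mj_network", gml)

  dip <- assign_diplotypes(G, samples, tag_panel)
  dose <- diplotype_dose(dip)
  emit("diplotype_dose",
       write_tsv(dose$per_diplotype, file.path(cfg$out_dir, "diplotype_dose.tsv")))

  expr <- simulate_expression(truth, seed = child_seed(cfg$seed, "expr"))
  emit("expression",
       write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
                 file.path(cfg$out_dir, "expression.tsv")))
  Z <- normalize_expression(expr, covariates = samples[, c("sex", "stratum")])
  trend <- diplotype_trend(Z["TARGET", ], truth$score)
  eq <- data.frame(gene = "TARGET", slope = trend$slope, t = trend$t_stat,
                   p = trend$p, n = trend$n)
  emit("eqtl", write_tsv(eq, file.path(cfg$out_dir, "eqtl.tsv")))

  is_case <- samples$status == "case"
  de <- run_de(expr[, is_case, drop = FALSE], expr[, !is_case, drop = FALSE],
               cfg$de)
  emit("de", write_tsv(de, file.path(cfg$out_dir, "de.tsv")))

  ser <- simulate_serology(truth, seed = child_seed(cfg$seed, "serology"))
  Sn <- normalize_nfi(ser)
  groups <- ifelse(truth$score >= 4, "risk", "protective")
  enr <- group_enrichment(Sn, groups, fold_threshold = cfg$serology_fold)
  emit("serology",
       write_tsv(enr$antigens, file.path(cfg$out_dir, "serology.tsv")))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(panel = panel, sim = sim, qc = qc, variant_stats = vs,
                 assoc = assoc, cmh = cmh, haplotype_freqs = freqs,
                 haplotype_assoc = hassoc, network = net,
                 diplotype_dose = dose, eqtl = trend, de = de,
                 serology = enr, manifest = manifest))
}
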