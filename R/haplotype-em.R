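# EM haplotype-frequency estimation from unphased biallelic genotypes.
#
# Phase enumeration is progressive (site by site): each sample carries a list
# of ordered partial-haplotype pairs compatible with its genotype, and when
# the pair list grows past a trigger the current pairs are re-weighted by an
# interim EM fit and low-posterior pairs are pruned.  This keeps the
# enumeration tractable at ~19 het sites while reducing exactly to full
# enumeration on small problems (no pruning ever triggers there).

#' EM haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies under Hardy-Weinberg pairing,
#' via EM over phase-compatible haplotype pairs.  The E-step weights an
#' ordered pair (h1, h2) by `f(h1) f(h2)` (each unordered heterozygous pair
#' appears as both orderings, which supplies the factor 2); the M-step
#' re-estimates frequencies from expected haplotype counts.  Frequencies are
#' initialized at the product of single-site allele frequencies; convergence
#' when `max |delta f| < tol` or `max_iter` iterations.  The observed-data
#' log-likelihood is asserted non-decreasing at every iteration.
#'
#' @param G samples x sites matrix of 0/1/2 codes (NA = missing).  Sites with
#'   no called genotypes are dropped with a warning; samples missing more
#'   than `max_missing` of the remaining sites are excluded.
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param min_freq haplotypes below this frequency are pruned from the
#'   output table (default 1e-6).
#' @param max_missing maximum fraction of missing tag sites per sample
#'   (default 0.2); missing sites of retained samples are marginalized in
#'   the phase enumeration.
#' @param prune_trigger total ordered-pair count above which interim pruning
#'   runs during enumeration (default 20000).
#' @param prune_tol pairs with interim posterior below `prune_tol` times the
#'   sample's best pair are discarded (default 1e-6).
#' @return a `haplotype_table` data.frame (haplotype string, freq,
#'   expected_count) sorted by decreasing frequency, with attributes:
#'   `loglik` (final observed-data log-likelihood), `n_samples`, `sites`,
#'   `assignments` (per-sample maximum-posterior phase: hap_a, hap_b,
#'   posterior) and `low_confidence` (TRUE when phase posteriors stay
#'   ambiguous, e.g. the all-double-heterozygote likelihood saddle).
#' @export
em_haplotype_frequencies <- function(G, tol = 1e-8, max_iter = 1000L,
                                     min_freq = 1e-6, max_missing = 0.2,
                                     prune_trigger = 20000L,
                                     prune_tol = 1e-6) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("s%d", seq_len(ncol(G)))
  all_na <- colSums(!is.na(G)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " site(s) with no called genotypes")
    G <- G[, !all_na, drop = FALSE]
  }
  if (ncol(G) == 0L) stop_arg("no usable sites")
  miss_frac <- rowMeans(is.na(G))
  keep <- miss_frac <= max_missing
  if (!all(keep)) {
    warning("excluding ", sum(!keep),
            " sample(s) with > ", 100 * max_missing, "% missing tag sites")
    G <- G[keep, , drop = FALSE]
  }
  n <- nrow(G)
  if (n == 0L) stop_arg("no usable samples")
  S <- ncol(G)

  # product-of-allele-frequency initial value for a haplotype string
  alt_f <- colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
  prod_init <- function(hstrs) {
    vapply(hstrs, function(s) {
      bits <- string_to_hap(s)
      prod(ifelse(bits == 1L, alt_f, 1 - alt_f))
    }, numeric(1))
  }

  em_fit <- function(pairs_a, pairs_b, owner, hap_strs, f0, iters, tol,
                     assert_monotone = FALSE) {
    # pairs_a/pairs_b: integer haplotype indices per ordered pair;
    # owner: sample index per pair
    f <- f0 / sum(f0)
    ll_prev <- -Inf
    for (it in seq_len(iters)) {
      w <- f[pairs_a] * f[pairs_b]
      tot <- vapply(split(w, owner), sum, numeric(1))
      ll <- sum(log(tot))
      if (assert_monotone && ll < ll_prev - 1e-7 * max(1, abs(ll_prev)))
        stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
      ll_prev <- ll
      post <- w / tot[match(owner, names(tot))]
      cnt <- numeric(length(hap_strs))
      ca <- tapply(post, pairs_a, sum)
      cb <- tapply(post, pairs_b, sum)
      cnt[as.integer(names(ca))] <- cnt[as.integer(names(ca))] + ca
      cnt[as.integer(names(cb))] <- cnt[as.integer(names(cb))] + cb
      f_new <- cnt / sum(cnt)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    list(f = f, post = post, loglik = ll_prev, counts = cnt)
  }

  # progressive expansion
  hap_strs <- ""
  pairs_a <- rep(1L, n)
  pairs_b <- rep(1L, n)
  owner <- seq_len(n)
  for (j in seq_len(S)) {
    g <- G[owner, j]
    ext <- function(idx, bit) {
      s2 <- paste0(hap_strs[idx], bit)
      s2
    }
    # expansion per genotype code
    hom0 <- which(!is.na(g) & g == 0L)
    hom2 <- which(!is.na(g) & g == 2L)
    het <- which(!is.na(g) & g == 1L)
    mis <- which(is.na(g))
    na_str <- nb_str <- no <- list()
    add <- function(sa, sb, ow) {
      na_str[[length(na_str) + 1L]] <<- sa
      nb_str[[length(nb_str) + 1L]] <<- sb
      no[[length(no) + 1L]] <<- ow
    }
    if (length(hom0)) add(ext(pairs_a[hom0], "0"), ext(pairs_b[hom0], "0"), owner[hom0])
    if (length(hom2)) add(ext(pairs_a[hom2], "1"), ext(pairs_b[hom2], "1"), owner[hom2])
    if (length(het)) {
      add(ext(pairs_a[het], "0"), ext(pairs_b[het], "1"), owner[het])
      add(ext(pairs_a[het], "1"), ext(pairs_b[het], "0"), owner[het])
    }
    if (length(mis)) {
      for (ba in c("0", "1")) for (bb in c("0", "1"))
        add(ext(pairs_a[mis], ba), ext(pairs_b[mis], bb), owner[mis])
    }
    sa <- unlist(na_str, use.names = FALSE)
    sb <- unlist(nb_str, use.names = FALSE)
    owner <- unlist(no, use.names = FALSE)
    hap_strs <- unique(c(sa, sb))
    pairs_a <- match(sa, hap_strs)
    pairs_b <- match(sb, hap_strs)

    if (length(pairs_a) > prune_trigger && j < S) {
      fit <- em_fit(pairs_a, pairs_b, owner, hap_strs,
                    prod_init(substr_init(hap_strs)), iters = 15L, tol = 1e-4)
      best <- tapply(fit$post, owner, max)
      keep_pair <- fit$post >= prune_tol * best[match(owner, names(best))]
      pairs_a <- pairs_a[keep_pair]
      pairs_b <- pairs_b[keep_pair]
      owner <- owner[keep_pair]
      used <- sort(unique(c(pairs_a, pairs_b)))
      hap_strs <- hap_strs[used]
      pairs_a <- match(used, used)[match(pairs_a, used)]
      pairs_b <- match(used, used)[match(pairs_b, used)]
    }
  }

  fit <- em_fit(pairs_a, pairs_b, owner, hap_strs, prod_init(hap_strs),
                iters = max_iter, tol = tol, assert_monotone = TRUE)
  f <- fit$f
  counts <- fit$counts

  # maximum-posterior unordered phase per sample
  key_lo <- pmin(pairs_a, pairs_b)
  key_hi <- pmax(pairs_a, pairs_b)
  pk <- paste(owner, key_lo, key_hi)
  agg <- tapply(fit$post, pk, sum)
  first <- !duplicated(pk)
  upost <- as.numeric(agg[pk[first]])
  uown <- owner[first]
  ulo <- key_lo[first]; uhi <- key_hi[first]
  best_i <- vapply(split(seq_along(uown), uown),
                   function(ix) ix[which.max(upost[ix])], 1L)
  assignments <- data.frame(
    sample = rownames(G) %||% as.character(seq_len(n)),
    hap_a = hap_strs[ulo[best_i]][order(uown[best_i])],
    hap_b = hap_strs[uhi[best_i]][order(uown[best_i])],
    posterior = upost[best_i][order(uown[best_i])],
    stringsAsFactors = FALSE
  )
  low_conf <- mean(assignments$posterior) < 0.6

  ord <- order(f, decreasing = TRUE)
  tab <- data.frame(haplotype = hap_strs[ord], freq = f[ord],
                    expected_count = counts[ord], stringsAsFactors = FALSE)
  tab <- tab[tab$freq >= min_freq, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("haplotype_table", "data.frame"),
            loglik = fit$loglik, n_samples = n, sites = colnames(G),
            assignments = assignments, low_confidence = low_conf)
}

# initial frequencies for partial strings (same product form)
substr_init <- function(hstrs) hstrs

#' Pairwise linkage disequilibrium from two-site haplotype frequencies
#'
#' @param f11,f10,f01,f00 haplotype frequencies (1 = alternate allele at the
#'   site); must sum to 1.
#' @return list with `D`, `Dprime`, `r2`, and the two alternate-allele
#'   frequencies `pA`, `pB`; all `NA` with `monomorphic = TRUE` when either
#'   site is monomorphic.
#' @export
ld_pair <- function(f11, f10, f01, f00) {
  f <- c(f11, f10, f01, f00)
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-6)
    stop_arg("haplotype frequencies must be non-negative and sum to 1")
  pA <- f11 + f10
  pB <- f11 + f01
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                pA = pA, pB = pB, monomorphic = TRUE))
  }
  D <- f11 - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, Dprime = Dprime, r2 = r2, pA = pA, pB = pB, monomorphic = FALSE)
}

#' Pairwise LD between two variants of a genotype matrix
#'
#' Estimates the four two-site haplotype frequencies by EM and returns
#' [ld_pair()] on them.
#'
#' @param G samples x variants genotype matrix.
#' @param i,j column names or indices of the two variants.
#' @return as [ld_pair()].
#' @export
ld_genotypes <- function(G, i, j) {
  sub <- G[, c(i, j), drop = FALSE]
  tab <- suppressWarnings(
    em_haplotype_frequencies(sub, max_missing = 1, min_freq = 0)
  )
  fget <- function(h) {
    k <- match(h, tab$haplotype)
    if (is.na(k)) 0 else tab$freq[k]
  }
  ld_pair(fget("11"), fget("10"), fget("01"), fget("00"))
}

#' Select the tag set in strong LD with a peak variant
#'
#' Returns all variants whose pairwise D' with the peak is at least
#' `threshold` (inclusive), ordered by position; the peak itself is always
#' included (D' with itself is 1).  Monomorphic variants are never selected.
#'
#' @param G samples x variants genotype matrix; an optional `position`
#'   attribute (one value per column) orders the output.
#' @param peak_variant column name of the peak.
#' @param threshold minimum D' (default 0.8).
#' @return data.frame: variant_id, position, Dprime, r2, ordered by position.
#' @export
select_tag_set <- function(G, peak_variant, threshold = 0.8) {
  if (!peak_variant %in% colnames(G)) stop_arg("peak variant not found")
  pos <- attr(G, "position") %||% seq_len(ncol(G))
  names(pos) <- colnames(G)
  rows <- lapply(colnames(G), function(v) {
    if (v == peak_variant)
      return(data.frame(variant_id = v, position = pos[[v]],
                        Dprime = 1, r2 = 1, stringsAsFactors = FALSE))
    ld <- ld_genotypes(G, v, peak_variant)
    data.frame(variant_id = v, position = pos[[v]],
               Dprime = ld$Dprime, r2 = ld$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$variant_id == peak_variant |      # peak always included
    (!is.na(out$Dprime) & out$Dprime >= threshold)
  out <- out[keep, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Label estimated haplotypes against a reference panel
#'
#' Hamming-nearest match to the panel haplotypes; ties broken toward the
#' lexicographically smallest label; haplotypes farther than `max_mismatch`
#' sites from every panel haplotype are labelled `"OTHER"`.
#'
#' @param hap_strings character haplotype strings ("0"/"1" per site).
#' @param panel a `haplotype_panel` with matching `n_sites`.
#' @param max_mismatch maximum Hamming distance for a label (default 2).
#' @return character vector of labels.
#' @export
label_haplotypes <- function(hap_strings, panel, max_mismatch = 2L) {
  pm <- do.call(rbind, panel$haplotypes)
  labs <- sort(names(panel$haplotypes))
  pm <- pm[labs, , drop = FALSE]
  vapply(hap_strings, function(s) {
    h <- string_to_hap(s)
    if (length(h) != ncol(pm)) stop_arg("haplotype length does not match panel")
    d <- apply(pm, 1L, function(r) sum(r != h))
    if (min(d) > max_mismatch) "OTHER" else labs[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
}
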