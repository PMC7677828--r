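# Median-joining haplotype networks over 0/1 haplotype vectors.
#
# The construction iterates: (1) a minimum-spanning network (all Kruskal-
# minimal links between components, relaxed by epsilon) under Hamming
# distance; (2) sitewise-majority (Steiner) medians of connected triplets
# added as zero-frequency nodes; until no novel median appears.  Obsolete
# medians (on no shortest path between observed haplotypes) are removed and
# the network rebuilt.

# minimum-spanning-network edges: an edge of cost c is kept iff its
# endpoints lie in different components of the graph of all kept edges with
# cost < c - epsilon (epsilon = 0 gives the standard MSN, a superset of
# every MST)
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n == 1L) return(matrix(integer(0), 0L, 2L))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  costs <- D[pairs]
  keep <- logical(nrow(pairs))
  for (cst in sort(unique(costs))) {
    # components induced by already-kept links of cost < cst - epsilon;
    # every cost-cst link joining two such components is kept (all minimal
    # alternatives survive, unlike a plain MST)
    comp <- seq_len(n)
    for (e in which(keep & costs < cst - epsilon)) {
      ca <- comp[pairs[e, 1L]]; cb <- comp[pairs[e, 2L]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    lvl <- which(costs == cst)
    keep[lvl[comp[pairs[lvl, 1L]] != comp[pairs[lvl, 2L]]]] <- TRUE
  }
  pairs[keep, , drop = FALSE]
}

sitewise_median <- function(a, b, c) {
  # majority vote per site; a tie (possible only with non-0/1 input) goes to
  # the reference allele 0
  as.integer((a + b + c) >= 2L)
}

#' Build a median-joining haplotype network
#'
#' @param haplotypes character vector of haplotype strings ("0"/"1" per
#'   site) or a list/matrix of 0/1 vectors of equal length; at least two
#'   distinct haplotypes.
#' @param counts optional named (or aligned) observed counts per haplotype.
#' @param epsilon non-negative connection-cost relaxation (default 0).
#' @param max_iterations maximum median-insertion sweeps (default 50).
#' @param exhaustive_triplets compute medians over all node triplets instead
#'   of connected triplets only (default FALSE).
#' @return an `mj_graph`: list with `nodes` (haplotype, label, count,
#'   is_median), `edges` (from, to, sites = comma-joined differing site
#'   indices, weight = Hamming distance) and `graph` (an igraph object).
#' @export
build_mj_network <- function(haplotypes, counts = NULL, epsilon = 0,
                             max_iterations = 50L,
                             exhaustive_triplets = FALSE) {
  if (epsilon < 0) stop_arg("`epsilon` must be >= 0")
  if (is.matrix(haplotypes))
    haplotypes <- apply(haplotypes, 1L, hap_to_string)
  if (is.list(haplotypes))
    haplotypes <- vapply(haplotypes, hap_to_string, character(1))
  haplotypes <- as.character(haplotypes)
  if (length(unique(nchar(haplotypes))) != 1L)
    stop_arg("haplotypes must all have the same length")
  if (is.null(counts)) counts <- rep(1, length(haplotypes))
  counts <- tapply(counts, haplotypes, sum)
  obs <- sort(names(counts))                # canonical order: by bit-vector
  if (length(obs) < 2L) stop_arg("need at least two distinct haplotypes")
  H <- do.call(rbind, lapply(obs, string_to_hap))
  is_median <- rep(FALSE, length(obs))

  dist_mat <- function(H) {
    n <- nrow(H)
    D <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i < j) D[i, j] <- D[j, i] <- sum(H[i, ] != H[j, ])
    D
  }

  edges <- NULL
  for (iter in seq_len(max_iterations)) {
    D <- dist_mat(H)
    edges <- msn_edges(D, epsilon)
    adj <- vector("list", nrow(H))
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    new_meds <- character(0)
    n <- nrow(H)
    trip <- if (exhaustive_triplets) {
      if (n >= 3L) utils::combn(n, 3L, simplify = FALSE) else list()
    } else {
      # connected triplets: u with two linked neighbours, or a linked path
      out <- list()
      for (u in seq_len(n)) {
        nb <- adj[[u]]
        if (length(nb) >= 2L) {
          cmb <- utils::combn(sort(unique(nb)), 2L)
          for (k in seq_len(ncol(cmb)))
            out[[length(out) + 1L]] <- c(u, cmb[1L, k], cmb[2L, k])
        }
      }
      out
    }
    for (t in trip) {
      m <- sitewise_median(H[t[1L], ], H[t[2L], ], H[t[3L], ])
      ms <- hap_to_string(m)
      if (!(ms %in% c(apply(H, 1L, hap_to_string), new_meds)))
        new_meds <- c(new_meds, ms)
    }
    if (!length(new_meds)) break
    new_meds <- sort(unique(new_meds))
    H <- rbind(H, do.call(rbind, lapply(new_meds, string_to_hap)))
    is_median <- c(is_median, rep(TRUE, length(new_meds)))
  }

  # remove medians on no shortest path between observed nodes
  repeat {
    D <- dist_mat(H)
    edges <- msn_edges(D, epsilon)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < nrow(H))
      g <- igraph::add_vertices(g, nrow(H) - igraph::vcount(g))
    igraph::E(g)$weight <- D[edges]
    gd <- igraph::distances(g)
    obs_idx <- which(!is_median)
    useful <- !is_median
    for (m in which(is_median)) {
      for (a in obs_idx) {
        da <- gd[a, m]
        if (!is.finite(da)) next
        if (any(abs(da + gd[m, obs_idx] - gd[a, obs_idx]) < 1e-9 &
                obs_idx != a)) { useful[m] <- TRUE; break }
      }
    }
    if (all(useful)) break
    H <- H[useful, , drop = FALSE]
    is_median <- is_median[useful]
  }

  strs <- apply(H, 1L, hap_to_string)
  node_counts <- ifelse(is_median, 0, as.numeric(counts[strs]))
  node_counts[is.na(node_counts)] <- 0
  med_i <- cumsum(is_median)
  labels <- ifelse(is_median, paste0("median", med_i), strs)
  sites <- vapply(seq_len(nrow(edges)), function(k) {
    paste(which(H[edges[k, 1L], ] != H[edges[k, 2L], ]), collapse = ",")
  }, character(1))
  nodes <- data.frame(haplotype = strs, label = labels, count = node_counts,
                      is_median = is_median, stringsAsFactors = FALSE)
  edf <- data.frame(from = strs[edges[, 1L]], to = strs[edges[, 2L]],
                    sites = sites,
                    weight = D[edges],
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edf, graph = g), class = "mj_graph")
}

#' Annotate network nodes with case/control composition
#'
#' @param net an `mj_graph`.
#' @param case_counts,control_counts named numerics (haplotype string ->
#'   count).
#' @return the network with `case_count`, `control_count`, `case_fraction`
#'   (NA for medians and zero-total nodes) and `size` (total count) added to
#'   `nodes` and to the igraph vertex attributes.
#' @export
annotate_nodes <- function(net, case_counts, control_counts) {
  if (any(case_counts < 0) || any(control_counts < 0))
    stop_arg("counts must be non-negative")
  nd <- net$nodes
  cc <- ifelse(nd$is_median, 0,
               ifelse(is.na(case_counts[nd$haplotype]), 0,
                      case_counts[nd$haplotype]))
  ct <- ifelse(nd$is_median, 0,
               ifelse(is.na(control_counts[nd$haplotype]), 0,
                      control_counts[nd$haplotype]))
  tot <- cc + ct
  nd$case_count <- as.numeric(cc)
  nd$control_count <- as.numeric(ct)
  nd$size <- as.numeric(tot)
  nd$case_fraction <- ifelse(nd$is_median | tot == 0, NA_real_, cc / tot)
  net$nodes <- nd
  g <- net$graph
  igraph::V(g)$case_count <- nd$case_count
  igraph::V(g)$control_count <- nd$control_count
  igraph::V(g)$case_fraction <- nd$case_fraction
  igraph::V(g)$size <- nd$size
  net$graph <- g
  net
}

#' Export a median-joining network
#'
#' @param net an `mj_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_mj_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- net$graph
  # igraph's writers reject logical/NA attributes in some formats
  igraph::V(g)$is_median <- as.integer(net$nodes$is_median)
  if (!is.null(igraph::V(g)$case_fraction))
    igraph::V(g)$case_fraction[is.na(igraph::V(g)$case_fraction)] <- -1
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
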