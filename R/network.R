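#' Filter and merge pooled tables into network candidates
#'
#' Keeps, per domain, the OTUs with relative abundance strictly above
#' `threshold` (default 1%) in at least one habitat — the step that removes
#' poorly represented OTUs and keeps network complexity manageable — then
#' merges the domains into one table over the shared habitat columns. OTU
#' ids colliding across domains are prefixed with the domain.
#'
#' @param tables Named list of pooled `otu_tbl`s (names = domains).
#' @param threshold Relative-abundance cut, in (0, 1).
#' @return A merged `otu_tbl` with a `domain` column.
#' @export
network_candidate_filter <- function(tables, threshold = 0.01) {
  stopifnot(is.list(tables), length(tables) >= 1)
  habs <- lapply(tables, sample_ids)
  if (length(unique(lapply(habs, sort))) != 1) {
    stop("habitat columns differ between domain tables", call. = FALSE)
  }
  habs <- sort(habs[[1]])
  kept <- lapply(tables, main_otu_filter, threshold = threshold)
  ids <- unlist(lapply(kept, `[[`, "otu_id"))
  prefix <- anyDuplicated(ids) > 0
  merged <- dplyr::bind_rows(lapply(kept, function(t) {
    d <- otu_domain(t)
    out <- tibble::tibble(
      otu_id = if (prefix) paste(d, t$otu_id, sep = ":") else t$otu_id,
      domain = d
    )
    dplyr::bind_cols(out, t[, habs])
  }))
  otu_table(merged, "multi", validate = FALSE)
}

#' All pairwise Spearman correlations between OTU profiles
#'
#' Computes tie-corrected Spearman rho (Pearson correlation of mid-ranks)
#' between every pair of OTU rows over the habitat columns, with a one-sided
#' p-value for positive association by default (the edge rule only keeps
#' positive correlations; `alternative = "two.sided"` is available).
#'
#' Two p-value engines:
#' * `t_approx` — the t statistic `rho * sqrt((n-2)/(1-rho^2))` on n-2
#'   degrees of freedom (the standard large-sample approximation), after
#'   shrinking rho toward zero by one rank-lattice step to compensate the
#'   discreteness of the permutation null at small n (negligible at the
#'   21-habitat scale).
#' * `exact_perm` — full enumeration of all n! rank permutations when
#'   n <= 8 (exact null distribution, tie-aware), otherwise `n_mc` Monte
#'   Carlo permutations with the add-one estimator.
#'
#' Pairs involving a constant profile (zero rank variance) have no defined
#' rho and are skipped with a message.
#'
#' @param tbl Merged candidate `otu_tbl` (rows OTUs, columns habitats).
#' @param method `"t_approx"` or `"exact_perm"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param n_mc Monte Carlo permutations when exact enumeration is infeasible.
#' @return Tibble of `otu_a`, `otu_b`, `rho`, `p_value`, `n` for every
#'   computable unordered pair.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' colnames(m) <- paste0("h", 1:4)
#' spearman_all_pairs(otu_table(m, "bacteria", validate = FALSE),
#'                    method = "exact_perm")  # rho 0.8, p 4/24
#' @export
spearman_all_pairs <- function(tbl, method = c("t_approx", "exact_perm"),
                               alternative = c("greater", "two.sided"),
                               n_mc = 10000) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  m <- as_otu_matrix(tbl)
  n <- ncol(m)
  if (n < 4) stop("need at least 4 habitat observations", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 OTUs", call. = FALSE)
  rk <- t(apply(m, 1, rank))  # mid-ranks
  const <- apply(rk, 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    message("skipping ", sum(const), " constant profile(s): ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    rk <- rk[!const, , drop = FALSE]
    if (nrow(rk) < 2) stop("fewer than 2 non-constant profiles", call. = FALSE)
  }
  rho <- stats::cor(t(rk))  # Pearson on ranks = tie-corrected Spearman
  pair <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[pair]
  p <- if (method == "t_approx") {
    spearman_p_t(r, n, alternative)
  } else {
    vapply(seq_len(nrow(pair)), function(k) {
      spearman_p_perm(rk[pair[k, 1], ], rk[pair[k, 2], ], alternative, n_mc)
    }, numeric(1))
  }
  tibble::tibble(otu_a = rownames(rk)[pair[, 1]], otu_b = rownames(rk)[pair[, 2]],
                 rho = r, p_value = p, n = n)
}

# t approximation with one lattice-step shrinkage of rho toward zero:
# the rank lattice is discrete (spacing 6/(n(n^2-1)) without ties) and the
# plain t tail underestimates the permutation tail at small n; shrinking by
# one step keeps tail p-values close to exact enumeration while changing
# rho by < 0.001 at the 21-habitat scale of real analyses.
spearman_p_t <- function(r, n, alternative) {
  r <- pmin(pmax(r, -1), 1)
  r <- sign(r) * pmax(abs(r) - 6 / (n * (n^2 - 1)), 0)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  if (alternative == "greater") {
    stats::pt(t, df = n - 2, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
}

spearman_p_perm <- function(rx, ry, alternative, n_mc) {
  n <- length(rx)
  obs <- stats::cor(rx, ry)
  eps <- 1e-12
  hit <- function(s) {
    if (alternative == "greater") s >= obs - eps else abs(s) >= abs(obs) - eps
  }
  # rho under permutation is affine in the cross-product sum(rx * ry[perm]),
  # so all permutation statistics come from one matrix product
  perm_rho <- function(perm_idx) {
    s <- matrix(ry[perm_idx], nrow(perm_idx)) %*% rx
    (s / (n - 1) - n * mean(rx) * mean(ry) / (n - 1)) /
      (stats::sd(rx) * stats::sd(ry))
  }
  if (n <= 8) {
    mean(hit(perm_rho(all_permutations(n))))
  } else {
    idx <- t(replicate(n_mc, sample.int(n)))
    (sum(hit(perm_rho(idx))) + 1) / (n_mc + 1)
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Select network edges by the dual rho/p rule
#'
#' An unordered OTU pair becomes an edge when its Spearman rho is strictly
#' greater than `rho_min` AND its p-value is below `alpha` (defaults 0.6
#' and 0.001) — strong, highly significant, positive association only. By
#' default the node set is the OTUs incident to at least one edge;
#' `keep_isolated = TRUE` retains every candidate OTU instead.
#'
#' @param correlations Tibble from [spearman_all_pairs()].
#' @param rho_min Correlation threshold, between -1 and 1.
#' @param alpha Significance threshold, in (0, 1).
#' @param nodes Optional candidate node tibble (`otu_id`, `domain`) used
#'   when `keep_isolated = TRUE`.
#' @param keep_isolated Keep candidate OTUs without edges as isolated nodes.
#' @return A `co_network`: list of `nodes` (with degrees), `edges` and the
#'   underlying `igraph` graph.
#' @export
edge_selection <- function(correlations, rho_min = 0.6, alpha = 0.001,
                           nodes = NULL, keep_isolated = FALSE) {
  if (rho_min < -1 || rho_min > 1) stop("rho_min must be in [-1, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  edges <- correlations[correlations$rho > rho_min & correlations$p_value < alpha, ]
  edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
  node_ids <- if (keep_isolated && !is.null(nodes)) {
    sort(unique(nodes$otu_id))
  } else {
    sort(unique(c(edges$otu_a, edges$otu_b)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b", "rho", "p_value")],
    directed = FALSE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE)
  )
  deg <- igraph::degree(g)
  node_tbl <- tibble::tibble(otu_id = node_ids, degree = as.integer(deg[node_ids]))
  if (!is.null(nodes) && "domain" %in% names(nodes)) {
    node_tbl$domain <- nodes$domain[match(node_tbl$otu_id, nodes$otu_id)]
    g <- igraph::set_vertex_attr(g, "domain", value = node_tbl$domain)
  }
  g <- igraph::set_vertex_attr(g, "degree", value = node_tbl$degree)
  out <- list(nodes = node_tbl, edges = edges, graph = g,
              rho_min = rho_min, alpha = alpha)
  class(out) <- "co_network"
  out
}

#' @export
print.co_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Co-occurrence network: %d nodes, %d edges (rho > %g, p < %g)\n  connectivity index E/N = %.2f, mean degree 2E/N = %.2f\n",
    g$n_nodes, g$n_edges, x$rho_min, x$alpha, g$connectivity_index, g$mean_degree))
  invisible(x)
}

#' Global and per-taxon network descriptors
#'
#' Computes node and edge counts, the connectivity index E/N (the "average
#' degree" convention of network summary tools that divide edges by nodes),
#' the graph-theoretic mean degree 2E/N, maximum degree with its OTUs, and
#' per-domain / per-taxon node counts and mean degrees, plus taxon-pair
#' summaries (edge counts between taxa and the endpoint-degree sums of the
#' strongest-connected pair per taxon pair — reported separately, as they
#' answer different questions).
#'
#' @param net A `co_network` whose nodes carry `domain` (use
#'   `edge_selection(..., nodes = )` or attach it beforehand).
#' @param tax Taxonomy tibble.
#' @param rank Rank for taxon grouping (default `"class"`).
#' @return List of tibbles: `global`, `by_domain`, `by_taxon`,
#'   `taxon_pairs`.
#' @export
network_descriptors <- function(net, tax, rank = "class") {
  nodes <- net$nodes
  strip <- function(ids) sub("^[a-z]+:", "", ids)
  ti <- match(strip(nodes$otu_id), tax$otu_id)
  nodes$domain <- tax$domain[ti]
  nodes$taxon <- if (nrow(nodes)) taxonomy_rank(tax[ti, ], rank) else character(0)
  g <- glance(net)
  by_domain <- dplyr::summarise(dplyr::group_by(nodes, .data$domain),
                                n_nodes = dplyr::n(),
                                mean_degree = mean(.data$degree), .groups = "drop")
  by_taxon <- dplyr::summarise(dplyr::group_by(nodes, .data$domain, .data$taxon),
                               n_nodes = dplyr::n(),
                               mean_degree = mean(.data$degree), .groups = "drop")
  edges <- net$edges
  if (nrow(edges)) {
    ta <- nodes$taxon[match(edges$otu_a, nodes$otu_id)]
    tb <- nodes$taxon[match(edges$otu_b, nodes$otu_id)]
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    dsum <- nodes$degree[match(edges$otu_a, nodes$otu_id)] +
            nodes$degree[match(edges$otu_b, nodes$otu_id)]
    taxon_pairs <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(taxon_a = lo, taxon_b = hi, dsum = dsum),
                      .data$taxon_a, .data$taxon_b),
      n_edges = dplyr::n(), max_endpoint_degree_sum = max(.data$dsum),
      .groups = "drop")
  } else {
    taxon_pairs <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                                  n_edges = integer(),
                                  max_endpoint_degree_sum = numeric())
  }
  list(global = g, by_domain = by_domain, by_taxon = by_taxon,
       taxon_pairs = taxon_pairs)
}

#' Build the co-occurrence network from pooled tables in one call
#'
#' Convenience wrapper: [network_candidate_filter()] then
#' [spearman_all_pairs()] then [edge_selection()].
#'
#' @param tables Named list of pooled per-domain `otu_tbl`s.
#' @param threshold Candidate relative-abundance cut (0.01).
#' @param rho_min,alpha Edge thresholds (0.6, 0.001).
#' @param method p-value engine for [spearman_all_pairs()].
#' @param keep_isolated Keep candidate OTUs without edges.
#' @return A `co_network`.
#' @export
build_network <- function(tables, threshold = 0.01, rho_min = 0.6, alpha = 0.001,
                          method = "t_approx", keep_isolated = FALSE) {
  cand <- network_candidate_filter(tables, threshold)
  cors <- spearman_all_pairs(cand, method = method)
  edge_selection(cors, rho_min = rho_min, alpha = alpha,
                 nodes = cand[, c("otu_id", "domain")],
                 keep_isolated = keep_isolated)
}
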