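#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bray-Curtis distance object into sample pairs
#' @param x A `bc_dist`.
#' @param ... Unused.
#' @return Tibble: `sample_a`, `sample_b`, `distance` (one row per
#'   unordered pair).
#' @export
tidy.bc_dist <- function(x, ...) {
  m <- as.matrix(x)
  pair <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(m)[pair[, 1]],
                 sample_b = colnames(m)[pair[, 2]],
                 distance = m[pair])
}

#' Tidy a replicate QC result into one row per distance
#' @param x A `replicate_qc`.
#' @param ... Unused.
#' @return Tibble: `comparison` (within/between), `distance`.
#' @export
tidy.replicate_qc <- function(x, ...) {
  tibble::tibble(
    comparison = rep(c("within", "between"), c(length(x$within), length(x$between))),
    distance = c(x$within, x$between)
  )
}

#' One-row summary of a replicate QC test
#' @param x A `replicate_qc`.
#' @param ... Unused.
#' @return Tibble with means, counts, Welch t, df, p and the pass flag.
#' @export
glance.replicate_qc <- function(x, ...) {
  tibble::tibble(
    mean_within = mean(x$within), mean_between = mean(x$between),
    n_within = length(x$within), n_between = length(x$between),
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    alpha = x$alpha, passed = x$passed
  )
}

#' Tidy a habitat dendrogram into its merge steps
#' @param x A `habitat_dendro`.
#' @param ... Unused.
#' @return Tibble: `step`, `height`, `members` (list column of leaf sets).
#' @export
tidy.habitat_dendro <- function(x, ...) {
  h <- x$hclust
  leafsets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    leafsets[[i]] <- sort(unlist(lapply(h$merge[i, ], function(j) {
      if (j < 0) h$labels[-j] else leafsets[[j]]
    })))
  }
  tibble::tibble(step = seq_along(h$height), height = h$height,
                 members = leafsets)
}

#' One-row summary of a habitat dendrogram
#' @param x A `habitat_dendro`.
#' @param ... Unused.
#' @export
glance.habitat_dendro <- function(x, ...) {
  tibble::tibble(n_habitats = length(x$hclust$labels), linkage = x$linkage,
                 root_height = max(x$hclust$height))
}

#' Tidy a co-occurrence network into its edge list
#' @param x A `co_network`.
#' @param ... Unused.
#' @export
tidy.co_network <- function(x, ...) tibble::as_tibble(x$edges)

#' Global descriptors of a co-occurrence network
#'
#' `connectivity_index` is E/N (the edges-per-node "average degree"
#' convention of common network summary tools); `mean_degree` is the
#' graph-theoretic 2E/N. Both are reported deliberately.
#'
#' @param x A `co_network`.
#' @param ... Unused.
#' @export
glance.co_network <- function(x, ...) {
  n <- nrow(x$nodes); e <- nrow(x$edges)
  top <- if (n) x$nodes$otu_id[x$nodes$degree == max(x$nodes$degree)] else character(0)
  tibble::tibble(
    n_nodes = n, n_edges = e,
    connectivity_index = if (n) e / n else 0,
    mean_degree = if (n) 2 * e / n else 0,
    max_degree = if (n) max(x$nodes$degree) else 0L,
    max_degree_otus = paste(top, collapse = ",")
  )
}

#' Tidy a synthetic community into its ground truth
#' @param x A `synthetic_community`.
#' @param ... Unused.
#' @export
tidy.synthetic_community <- function(x, ...) x$truth

#' One-row summary of a synthetic community
#' @param x A `synthetic_community`.
#' @param ... Unused.
#' @export
glance.synthetic_community <- function(x, ...) {
  tibble::tibble(
    n_otus = nrow(x$truth), n_samples = nrow(x$metadata),
    n_habitats = length(unique(x$metadata$habitat_id)),
    reads_per_sample = x$spec$reads_per_sample,
    n_generalists = sum(x$truth$role == "generalist"),
    n_specialists = sum(x$truth$role == "specialist"),
    n_corr_pairs = sum(!is.na(x$truth$pair_id)) %/% 2L
  )
}
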