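#' Keep the "main" OTUs of a pooled table
#'
#' Retains OTUs whose relative abundance is strictly greater than
#' `threshold` in at least one habitat; applied per domain table. The
#' default 0.001 (1 per mille) defines the main community used for habitat
#' clustering; 0.01 (1 percent) is the stricter cut used for network
#' candidates.
#'
#' @param tbl A pooled `otu_tbl`.
#' @param threshold Relative-abundance cut, in (0, 1).
#' @return The filtered `otu_tbl` (counts unchanged, rows subset).
#' @export
main_otu_filter <- function(tbl, threshold = 0.001) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  rel <- as_otu_matrix(relative_abundance(tbl))
  keep <- apply(rel > threshold, 1, any)
  out <- tbl[keep, , drop = FALSE]
  attr(out, "domain") <- otu_domain(tbl)
  class(out) <- unique(c("otu_tbl", class(out)))
  out
}

#' Cluster pooled habitats by community dissimilarity
#'
#' Builds Bray-Curtis distances between habitats from the main-OTU relative
#' abundance profiles of one or several domain tables and agglomerates with
#' average linkage (UPGMA) by default. With `weight_domains = TRUE` each
#' domain's profile block is renormalised to equal total weight, so the
#' domain with most OTUs does not dominate the joint dissimilarity;
#' equivalently the joint Bray-Curtis is the mean of the per-domain ones.
#' Habitat columns are sorted lexicographically before agglomeration so
#' ties break deterministically.
#'
#' @param tables A pooled, filtered `otu_tbl` or a list of them (one per
#'   domain, identical habitat columns).
#' @param weight_domains Give each domain equal weight (default `TRUE`).
#' @param linkage `"average"` (UPGMA), `"single"` or `"complete"`.
#' @return A `habitat_dendro`: list with `hclust`, `dist`, `linkage`.
#' @export
cluster_habitats <- function(tables, weight_domains = TRUE,
                             linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(tables, "otu_tbl") || inherits(tables, "dist")) tables <- list(tables)
  if (inherits(tables[[1]], "dist")) {
    d <- tables[[1]]
  } else {
    habs <- lapply(tables, sample_ids)
    if (length(unique(lapply(habs, sort))) != 1) {
      stop("habitat columns differ between domain tables", call. = FALSE)
    }
    habs <- sort(habs[[1]])
    if (length(habs) < 2) stop("need at least two habitats to cluster", call. = FALSE)
    blocks <- lapply(tables, function(t) {
      p <- as_otu_matrix(relative_abundance(t))[, habs, drop = FALSE]
      if (weight_domains) p / length(tables) else p
    })
    stacked <- do.call(rbind, blocks)
    rownames(stacked) <- make.unique(unlist(lapply(blocks, rownames)))
    d <- bray_curtis(otu_table(stacked, "multi", validate = FALSE))
  }
  if (anyNA(d)) stop("NA in distance matrix", call. = FALSE)
  h <- stats::hclust(stats::as.dist(d), method = linkage)
  out <- list(hclust = h, dist = d, linkage = linkage)
  class(out) <- "habitat_dendro"
  out
}

#' @export
print.habitat_dendro <- function(x, ...) {
  cat("Habitat dendrogram (", x$linkage, " linkage, Bray-Curtis) over ",
      length(x$hclust$labels), " habitats\n", sep = "")
  invisible(x)
}

#' Do the given habitats form a clade?
#'
#' Checks whether some internal node of the dendrogram has exactly the
#' given habitat set as its leaves.
#'
#' @param dendro A `habitat_dendro`.
#' @param habitats Character vector of habitat ids.
#' @return `TRUE` if the set is a clade of the tree.
#' @export
is_habitat_clade <- function(dendro, habitats) {
  h <- dendro$hclust
  labs <- h$labels
  if (!all(habitats %in% labs)) stop("unknown habitat(s)", call. = FALSE)
  if (length(habitats) == length(labs)) return(TRUE)
  leafsets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    members <- unlist(lapply(h$merge[i, ], function(j) {
      if (j < 0) labs[-j] else leafsets[[j]]
    }))
    leafsets[[i]] <- members
    if (length(members) == length(habitats) && setequal(members, habitats)) return(TRUE)
  }
  FALSE
}

#' Cophenetic distances of a habitat dendrogram
#' @param dendro A `habitat_dendro`.
#' @return A `dist` of cophenetic (merge-height) distances.
#' @export
cophenetic_distances <- function(dendro) stats::cophenetic(dendro$hclust)

#' Aggregate relative abundance to a taxonomic rank
#'
#' Sums per-habitat relative abundances of all OTUs sharing a taxon at the
#' requested rank: the long-format data behind taxon dot plots. Aggregating
#' an unfiltered table conserves totals (each habitat sums to 1);
#' aggregating a filtered table sums to <= 1. OTUs without a resolved taxon
#' fall in an explicit "unclassified <domain>" bucket.
#'
#' @param tbl A pooled `otu_tbl`.
#' @param tax Taxonomy tibble (`otu_id`, `domain`, `lineage`).
#' @param rank `"domain"`, `"phylum"` or `"class"`.
#' @return Long tibble: `domain`, `taxon`, `habitat_id`, `rel_abundance`.
#' @export
taxon_aggregate <- function(tbl, tax, rank = "class") {
  if (!rank %in% c("domain", "phylum", "class")) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  missing <- setdiff(tbl$otu_id, tax$otu_id)
  if (length(missing)) {
    stop("OTU(s) absent from taxonomy: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  rel <- relative_abundance(tbl)
  tax_sub <- tax[match(rel$otu_id, tax$otu_id), ]
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(rel[, "otu_id"],
                     tibble::tibble(domain = tax_sub$domain,
                                    taxon = taxonomy_rank(tax_sub, rank)),
                     rel[, sample_ids(rel)]),
    -c("otu_id", "domain", "taxon"),
    names_to = "habitat_id", values_to = "rel_abundance"
  )
  dplyr::summarise(dplyr::group_by(long, .data$domain, .data$taxon, .data$habitat_id),
                   rel_abundance = sum(.data$rel_abundance), .groups = "drop")
}
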