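#' Read an OTU count table from TSV
#'
#' Expects a tab-separated file whose first column holds OTU ids and whose
#' header row holds sample ids. Counts are validated (integer, non-negative,
#' unique ids) on read.
#'
#' @param path Path to a TSV file.
#' @param domain Domain label for the table (`"bacteria"`, `"fungi"`,
#'   `"archaea"`).
#' @return An [otu_table()] tibble.
#' @export
read_otu_table <- function(path, domain) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2 || nrow(raw) == 0) stop("malformed OTU table: ", path, call. = FALSE)
  names(raw)[1] <- "otu_id"
  counts <- raw[-1]
  suppressWarnings(num <- lapply(counts, as.numeric))
  bad <- names(counts)[vapply(num, anyNA, logical(1))]
  if (length(bad)) stop("non-numeric count in column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tbl <- dplyr::bind_cols(tibble::tibble(otu_id = raw$otu_id), tibble::as_tibble(num))
  otu_table(tbl, domain)
}

#' Write an OTU table to TSV (canonical ordering)
#'
#' Rows are sorted by OTU id and sample columns lexicographically so output
#' is byte-reproducible regardless of in-memory order.
#'
#' @param tbl An `otu_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(tbl, path) {
  ids <- setdiff(names(tbl), sample_ids(tbl))
  out <- tbl[order(tbl$otu_id), c(ids, sort(sample_ids(tbl)))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated columns: `sample_id`, `site_code`, `layer_label`,
#' `biome_class`, `replicate_index`. A `habitat_id` is derived as
#' `site_code` + "-" + `layer_label` (e.g. `DH-Top`, `SH-2`); every
#' (habitat, replicate) pair must be unique and `biome_class` must be one of
#' soil, shore, freshwater, sediment.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the five input columns plus `habitat_id`.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), site_code = readr::col_character(),
    layer_label = readr::col_character(), biome_class = readr::col_character(),
    replicate_index = readr::col_integer()
  ), progress = FALSE)
  if (nrow(meta) == 0) stop("empty metadata file: ", path, call. = FALSE)
  validate_metadata(derive_habitat(meta))
}

derive_habitat <- function(meta) {
  meta$habitat_id <- paste(meta$site_code, meta$layer_label, sep = "-")
  meta
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "site_code", "layer_label", "biome_class",
            "replicate_index", "habitat_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- setdiff(unique(meta$biome_class), BIOMES)
  if (length(bad)) stop("unknown biome_class: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(meta$replicate_index < 1)) stop("replicate_index must be >= 1", call. = FALSE)
  key <- paste(meta$habitat_id, meta$replicate_index)
  if (anyDuplicated(key)) {
    stop("duplicated (habitat, replicate): ", key[duplicated(key)][1], call. = FALSE)
  }
  meta
}

#' Read an OTU taxonomy table
#'
#' Tab-separated columns: `otu_id`, `domain`, and a semicolon-delimited rank
#' path (phylum;class...). Missing ranks are filled with the explicit token
#' `"unclassified"`; an OTU repeated with conflicting lineages is an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `otu_id`, `domain`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tax) < 2) stop("malformed taxonomy file: ", path, call. = FALSE)
  names(tax)[1:2] <- c("otu_id", "domain")
  tax$lineage <- if (ncol(tax) >= 3) tax[[3]] else NA_character_
  tax$lineage[is.na(tax$lineage) | tax$lineage == ""] <- "unclassified"
  tax <- dplyr::distinct(tax[, c("otu_id", "domain", "lineage")])
  if (anyDuplicated(tax$otu_id)) {
    stop("conflicting lineages for OTU: ", tax$otu_id[duplicated(tax$otu_id)][1], call. = FALSE)
  }
  tax
}

#' Write a taxonomy table (canonical ordering)
#' @param tax Taxonomy tibble from [read_taxonomy()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  readr::write_tsv(tax[order(tax$otu_id), c("otu_id", "domain", "lineage")],
                   path, progress = FALSE)
  invisible(path)
}

#' Extract a named rank from a lineage string
#'
#' Lineages are semicolon paths ordered phylum then class. Absent levels
#' yield `"unclassified <domain>"` so aggregated abundance is conserved.
#'
#' @param tax Taxonomy tibble (`otu_id`, `domain`, `lineage`).
#' @param rank `"domain"`, `"phylum"` or `"class"`.
#' @return Character vector of taxon names aligned with `tax$otu_id`.
#' @export
taxonomy_rank <- function(tax, rank = c("class", "phylum", "domain")) {
  rank <- match.arg(rank)
  if (rank == "domain") return(tax$domain)
  idx <- match(rank, c("phylum", "class"))
  parts <- strsplit(tax$lineage, ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    v <- trimws(p)
    if (length(v) >= idx && nzchar(v[idx]) && v[idx] != "unclassified") v[idx] else NA_character_
  }, character(1))
  ifelse(is.na(out), paste("unclassified", tax$domain), out)
}

#' Write a habitat dendrogram as Newick
#'
#' Branch lengths follow the ultrametric half-height convention: two leaves
#' joined at Bray-Curtis height h sit at depth h/2 below their ancestor.
#'
#' @param dendro A `habitat_dendro` from [cluster_habitats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dendro, path) {
  phy <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a co-occurrence network
#'
#' Exports GraphML (node attributes: domain, taxon, degree; edge attribute:
#' rho) and/or an edge-list TSV (`otu_a`, `otu_b`, `rho`, `p_value`), rows
#' sorted for byte reproducibility.
#'
#' @param net A `co_network` from [edge_selection()].
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    e <- net$edges[order(net$edges$otu_a, net$edges$otu_b),
                   c("otu_a", "otu_b", "rho", "p_value")]
    readr::write_tsv(e, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a long-format table (canonical row ordering)
#' @param tbl A long tibble (e.g. from [taxon_aggregate()] or
#'   [breadth_summary()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(tbl, path) {
  ord <- do.call(order, unname(as.list(tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE])))
  readr::write_tsv(tbl[ord, , drop = FALSE], path, progress = FALSE)
  invisible(path)
}
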