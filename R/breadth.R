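#' Per-OTU occurrence over pooled habitats
#'
#' An OTU is detected in a habitat when its pooled count reaches
#' `min_count` (default 1 read, i.e. any detection). Occurrence is the
#' number of habitats where it is detected.
#'
#' @param tbl A pooled `otu_tbl`.
#' @param min_count Detection threshold in reads (>= 1).
#' @return Tibble: `otu_id`, `occurrence`, `habitats_detected` (list
#'   column of habitat ids).
#' @export
occurrence_profile <- function(tbl, min_count = 1) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  m <- as_otu_matrix(tbl)
  det <- m >= min_count
  tibble::tibble(
    otu_id = rownames(m),
    occurrence = as.integer(rowSums(det)),
    habitats_detected = lapply(seq_len(nrow(m)), function(i) colnames(m)[det[i, ]])
  )
}

#' Classify habitat breadth: generalist, intermediate or specialist
#'
#' Applies the occupancy rule of the gradient design: an OTU detected in at
#' least `generalist_min` of the `n_habitats` pooled habitats is a habitat
#' generalist (default 16 of 21), one detected in exactly one habitat is a
#' habitat specialist, everything in between is intermediate. OTUs never
#' detected are dropped.
#'
#' @param profiles Occurrence tibble from [occurrence_profile()].
#' @param n_habitats Number of pooled habitats in the design (21).
#' @param generalist_min Minimum occurrence for a generalist (16).
#' @return `profiles` with a `breadth_class` factor added, detected OTUs
#'   only.
#' @export
classify_breadth <- function(profiles, n_habitats = 21, generalist_min = 16) {
  if (generalist_min <= 1) stop("generalist_min must exceed 1", call. = FALSE)
  if (any(profiles$occurrence > n_habitats)) {
    stop("occurrence exceeds n_habitats", call. = FALSE)
  }
  out <- profiles[profiles$occurrence >= 1, , drop = FALSE]
  out$breadth_class <- factor(
    dplyr::case_when(
      out$occurrence >= generalist_min ~ "generalist",
      out$occurrence == 1 ~ "specialist",
      TRUE ~ "intermediate"
    ),
    levels = c("generalist", "intermediate", "specialist")
  )
  out
}

#' Long tables of generalist and specialist abundance
#'
#' The data behind the breadth dot plots: for each classified generalist or
#' specialist, the per-habitat relative abundance with an explicit
#' `detected` flag (generalists get one row per habitat so non-detections
#' can be marked; specialists only appear in the habitat where they occur),
#' labelled with domain and class-rank taxon.
#'
#' @param profiles Classified profiles from [classify_breadth()].
#' @param tbl The pooled `otu_tbl` the profiles came from (one domain or
#'   merged with a `domain` column resolvable through `tax`).
#' @param tax Taxonomy tibble.
#' @param min_count Detection threshold used for the profiles.
#' @return Long tibble: `otu_id`, `breadth_class`, `domain`, `taxon`,
#'   `habitat_id`, `rel_abundance`, `detected`.
#' @export
breadth_summary <- function(profiles, tbl, tax, min_count = 1) {
  rel <- as_otu_matrix(relative_abundance(tbl))
  cnt <- as_otu_matrix(tbl)
  keep <- profiles[profiles$breadth_class %in% c("generalist", "specialist"), ]
  tax_i <- match(keep$otu_id, tax$otu_id)
  taxon <- taxonomy_rank(tax[tax_i, ], "class")
  rows <- purrr::pmap_dfr(
    list(keep$otu_id, as.character(keep$breadth_class), tax$domain[tax_i], taxon),
    function(id, cls, dom, txn) {
      det <- cnt[id, ] >= min_count
      habs <- if (cls == "generalist") colnames(rel) else colnames(rel)[det]
      tibble::tibble(otu_id = id, breadth_class = cls, domain = dom, taxon = txn,
                     habitat_id = habs, rel_abundance = rel[id, habs],
                     detected = det[habs])
    })
  rows
}
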