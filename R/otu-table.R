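#' Build an OTU count table
#'
#' The package's universal currency: a wide tibble with an `otu_id` column,
#' one numeric column per sample (or per pooled habitat), and optionally a
#' `domain` column when tables from several microbial domains have been
#' merged. Counts are non-negative integers (sequence reads); all analysis
#' functions accept this shape.
#'
#' @param counts A numeric matrix (OTUs x samples) with rownames as OTU ids,
#'   or a data frame whose first column is `otu_id`.
#' @param domain Domain label for the whole table: one of `"bacteria"`,
#'   `"fungi"`, `"archaea"` (or `"multi"` for merged tables).
#' @param validate Check invariants (default `TRUE`).
#' @return A tibble of class `otu_tbl` with attribute `domain`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'             dimnames = list(c("b_1", "b_2"), c("s1", "s2")))
#' otu_table(m, "bacteria")
#' @export
otu_table <- function(counts, domain, validate = TRUE) {
  domain <- check_domain(domain)
  if (is.matrix(counts)) {
    stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
    tbl <- dplyr::bind_cols(
      tibble::tibble(otu_id = rownames(counts)),
      tibble::as_tibble(counts)
    )
  } else {
    tbl <- tibble::as_tibble(counts)
    if (names(tbl)[1] != "otu_id") names(tbl)[1] <- "otu_id"
  }
  tbl$otu_id <- as.character(tbl$otu_id)
  attr(tbl, "domain") <- domain
  class(tbl) <- unique(c("otu_tbl", class(tbl)))
  if (validate) {
    validate_otu_table(tbl)
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], function(v) as.integer(round(v)))
  }
  tbl
}

DOMAINS <- c("bacteria", "fungi", "archaea", "multi")
BIOMES  <- c("soil", "shore", "freshwater", "sediment")

check_domain <- function(domain) {
  domain <- match.arg(domain, DOMAINS)
  domain
}

#' Validate an OTU table
#'
#' Checks the table invariants: unique OTU ids, unique sample ids,
#' non-negative integer counts. All-zero sample columns are flagged with a
#' warning (they carry no community information and break relative
#' abundances).
#'
#' @param tbl An `otu_tbl`.
#' @return `tbl` invisibly; errors describe the first violated invariant.
#' @export
validate_otu_table <- function(tbl) {
  if (!"otu_id" %in% names(tbl)) stop("OTU table must have an 'otu_id' column", call. = FALSE)
  dup <- tbl$otu_id[duplicated(tbl$otu_id)]
  if (length(dup)) stop("duplicate OTU ids: ", paste(utils::head(dup, 3), collapse = ", "), call. = FALSE)
  m <- as_otu_matrix(tbl)
  if (ncol(m) == 0) stop("OTU table has no sample columns", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(m) || !is.numeric(m)) stop("counts must be numeric and non-missing", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count for OTU '", rownames(m)[bad[1]], "' in sample '",
         colnames(m)[bad[2]], "'", call. = FALSE)
  }
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integers", call. = FALSE)
  zero <- colnames(m)[colSums(m) == 0]
  if (length(zero)) warning("all-zero sample column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  invisible(tbl)
}

#' Extract the numeric matrix from an OTU table
#'
#' @param tbl An `otu_tbl` (or any tibble with `otu_id` plus numeric columns).
#' @return Numeric matrix, rows = OTUs (rownames from `otu_id`),
#'   columns = samples/habitats.
#' @export
as_otu_matrix <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  m <- as.matrix(tbl[, num, drop = FALSE])
  rownames(m) <- tbl$otu_id
  m
}

otu_domain <- function(tbl) {
  d <- attr(tbl, "domain")
  if (is.null(d)) "multi" else d
}

sample_ids <- function(tbl) colnames(as_otu_matrix(tbl))

rebuild_otu_tbl <- function(tbl, m) {
  out <- dplyr::bind_cols(
    tbl[, !vapply(tbl, is.numeric, logical(1)), drop = FALSE],
    tibble::as_tibble(m)
  )
  attr(out, "domain") <- otu_domain(tbl)
  class(out) <- unique(c("otu_tbl", class(out)))
  out
}

#' Per-sample relative abundances
#'
#' Divides every sample column by its total so each column sums to one.
#' Columns summing to zero are rejected by name: a sample with no reads has
#' no defined composition.
#'
#' @param tbl An `otu_tbl` of counts (raw or pooled).
#' @return A tibble of the same shape with proportions in place of counts.
#' @examples
#' m <- matrix(c(2L, 3L, 5L), 3, 1, dimnames = list(paste0("o", 1:3), "s1"))
#' relative_abundance(otu_table(m, "bacteria"))
#' @export
relative_abundance <- function(tbl) {
  m <- as_otu_matrix(tbl)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  rebuild_otu_tbl(tbl, sweep(m, 2, tot, "/"))
}

#' Merge OTU tables of one domain
#'
#' Unions tables that share a domain (e.g. two fungal marker datasets) over
#' the same sample columns, summing counts for OTU ids present in both.
#'
#' @param tables List of `otu_tbl`s with identical sample columns and one
#'   common domain label.
#' @return One merged `otu_tbl`.
#' @export
merge_otu_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  doms <- unique(vapply(tables, otu_domain, character(1)))
  if (length(doms) != 1) stop("tables must share one domain label", call. = FALSE)
  cols <- lapply(tables, sample_ids)
  if (length(unique(lapply(cols, sort))) != 1) stop("tables must share sample columns", call. = FALSE)
  long <- dplyr::bind_rows(lapply(tables, function(t) {
    tidyr::pivot_longer(t[, c("otu_id", cols[[1]])], -"otu_id",
                        names_to = "sample_id", values_to = "count")
  }))
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(long, .data$otu_id, .data$sample_id),
                     count = sum(.data$count), .groups = "drop"),
    names_from = "sample_id", values_from = "count"
  )
  if (length(tables) > 1) {
    message("merged ", length(tables), " ", doms, " tables into one (",
            nrow(wide), " OTUs)")
  }
  otu_table(wide, doms)
}
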