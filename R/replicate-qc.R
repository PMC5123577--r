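#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over OTUs, computed between
#' every pair of sample columns (via `vegan::vegdist`). By pipeline
#' convention profiles are relative abundances, which removes sequencing
#' depth artifacts; the function itself accepts any non-negative profiles.
#'
#' @param tbl An `otu_tbl` of counts or proportions.
#' @return A `bc_dist` (a `stats::dist` over samples); use `tidy()` for a
#'   long pair table or `as.matrix()` for the square form.
#' @examples
#' m <- matrix(c(2, 1, 0, 1, 1, 1), 3, 2,
#'             dimnames = list(paste0("o", 1:3), c("a", "b")))
#' as.matrix(bray_curtis(otu_table(m, "bacteria")))  # 1/3 off-diagonal
#' @export
bray_curtis <- function(tbl) {
  m <- as_otu_matrix(tbl)
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  d <- vegan::vegdist(t(m), method = "bray")
  class(d) <- c("bc_dist", class(d))
  d
}

#' Test whether replicates are more similar than non-replicates
#'
#' Pools all pairwise Bray-Curtis distances into within-habitat (replicate)
#' and between-habitat sets and runs a one-sided Welch t-test of
#' mean(within) < mean(between). A pass (at `alpha`) is the justification
#' for pooling replicates into one sample per habitat.
#'
#' @param dm A `bc_dist` over replicate-level samples.
#' @param meta Sample metadata with `sample_id` and `habitat_id`.
#' @param alpha Significance level (default 0.001).
#' @return A `replicate_qc` object; see [glance.replicate_qc()].
#' @export
replicate_distance_test <- function(dm, meta, alpha = 0.001) {
  m <- as.matrix(dm)
  ids <- rownames(m)
  hab <- meta$habitat_id[match(ids, meta$sample_id)]
  if (anyNA(hab)) {
    stop("sample(s) missing from metadata: ",
         paste(ids[is.na(hab)], collapse = ", "), call. = FALSE)
  }
  singles <- names(which(table(meta$habitat_id[meta$sample_id %in% ids]) == 1))
  if (length(singles)) {
    warning("habitat(s) with a single replicate excluded from the within set: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  pair <- which(upper.tri(m), arr.ind = TRUE)
  same <- hab[pair[, 1]] == hab[pair[, 2]]
  within <- m[pair[same, , drop = FALSE]]
  between <- m[pair[!same, , drop = FALSE]]
  if (length(within) == 0) stop("no within-habitat replicate pairs", call. = FALSE)
  se <- sqrt(stats::var(within) / length(within) + stats::var(between) / length(between))
  if (se == 0) {
    # both groups constant: the Welch statistic degenerates; the direction
    # of the mean difference decides
    diff <- mean(within) - mean(between)
    stat <- if (diff < 0) -Inf else if (diff > 0) Inf else 0
    res <- list(within = within, between = between, statistic = stat,
                p_value = if (diff < 0) 0 else 1, df = NA_real_, alpha = alpha,
                passed = diff < 0)
  } else {
    tt <- stats::t.test(within, between, alternative = "less", var.equal = FALSE)
    res <- list(within = within, between = between,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter), alpha = alpha,
                passed = mean(within) < mean(between) && tt$p.value < alpha)
  }
  class(res) <- "replicate_qc"
  res
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat(sprintf(
    "Replicate distance test (Welch, one-sided)\n  mean within  = %.4f (n = %d)\n  mean between = %.4f (n = %d)\n  t = %.3f, df = %.1f, p = %.3g -> %s at alpha = %g\n",
    mean(x$within), length(x$within), mean(x$between), length(x$between),
    x$statistic, x$df, x$p_value, if (x$passed) "PASS" else "FAIL", x$alpha))
  invisible(x)
}

#' Pool replicate samples into one column per habitat
#'
#' Sums counts elementwise over the replicates of each habitat, so an OTU
#' detected in any replicate is detected in the pooled habitat and total
#' reads are conserved. Habitat columns are ordered lexicographically.
#'
#' @param tbl A replicate-level `otu_tbl`.
#' @param meta Sample metadata mapping `sample_id` to `habitat_id`.
#' @return An `otu_tbl` with one column per habitat.
#' @export
pool_replicates <- function(tbl, meta) {
  m <- as_otu_matrix(tbl)
  hab <- meta$habitat_id[match(colnames(m), meta$sample_id)]
  if (anyNA(hab)) {
    stop("sample(s) missing from metadata: ",
         paste(colnames(m)[is.na(hab)], collapse = ", "), call. = FALSE)
  }
  habs <- sort(unique(hab))
  pooled <- vapply(habs, function(h) rowSums(m[, hab == h, drop = FALSE]),
                   numeric(nrow(m)))
  if (nrow(m) == 1) pooled <- matrix(pooled, 1, dimnames = list(rownames(m), habs))
  otu_table(pooled, otu_domain(tbl), validate = FALSE)
}
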