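# Independent oracles and small fixture builders used across the suite.

# Bray-Curtis by the definition, one pair at a time
bc_naive <- function(m) {
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
  }
  out
}

# UPGMA by direct definition: repeatedly merge the cluster pair with the
# smallest mean original-matrix distance; returns the cophenetic matrix.
upgma_oracle <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  cl <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(cl) > 1) {
    best <- c(Inf, 0, 0)
    for (a in seq_len(length(cl) - 1)) for (b in seq(a + 1, length(cl))) {
      d <- mean(D[cl[[a]], cl[[b]]])
      if (d < best[1]) best <- c(d, a, b)
    }
    coph[cl[[best[2]]], cl[[best[3]]]] <- best[1]
    coph[cl[[best[3]]], cl[[best[2]]]] <- best[1]
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
  }
  coph
}

# Welch two-sample t written out from the closed form (one-sided, x < y)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = pt(t, df))
}

# Small community spec so unit tests stay fast
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_otus = c(bacteria = 60, fungi = 30, archaea = 20),
         n_generalists = 4, n_specialists = 8, n_corr_pairs = 3, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# A tiny pooled table with exact relative abundances under control:
# columns are habitats, counts chosen so proportions are round numbers.
tiny_pooled <- function() {
  m <- matrix(c(
    4,    0,     # 0.002 in h1 -> kept at the 1 per mille rule
    2,    2,     # exactly 0.001 everywhere -> removed (strict inequality)
    1,    1,     # 0.0005 everywhere -> removed
    1993, 1997   # filler bringing each habitat to 2000 reads
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("keep", "edge", "low", "fill"), c("h1", "h2")))
  otu_table(m, "bacteria", validate = FALSE)
}

planted_pairs <- function(truth) {
  split(truth$otu_id[!is.na(truth$pair_id)], truth$pair_id[!is.na(truth$pair_id)])
}

pair_recovered <- function(net, pair) {
  key <- paste(min(pair), max(pair))
  key %in% paste(pmin(net$edges$otu_a, net$edges$otu_b),
                 pmax(net$edges$otu_a, net$edges$otu_b))
}
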