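test_that("Bray-Curtis matches its definition on hand cases", {
  m <- matrix(c(2, 1, 0, 1, 1, 1), 3, 2,
              dimnames = list(paste0("o", 1:3), c("x", "y")))
  d <- as.matrix(bray_curtis(otu_table(m, "bacteria", validate = FALSE)))
  expect_equal(d["x", "y"], 1 / 3)                      # (1+0+1)/(3+3)

  m2 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  d2 <- as.matrix(bray_curtis(otu_table(m2, "bacteria", validate = FALSE)))
  expect_equal(d2["x", "y"], 1)                         # disjoint supports
  expect_equal(unname(diag(d2)), c(0, 0))               # identity

  m3 <- cbind(m, z = c(0, 0, 0))
  expect_error(bray_curtis(otu_table(m3, "bacteria", validate = FALSE)), "z")
})

test_that("Bray-Curtis agrees with a naive double-loop oracle", {
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- matrix(rpois(200, 4) + rbinom(200, 1, 0.5), 20, 10,
                  dimnames = list(paste0("o", 1:20), paste0("s", 1:10)))
      m[1, ] <- m[1, ] + 1
      d <- as.matrix(bray_curtis(otu_table(m, "bacteria", validate = FALSE)))
      expect_lt(max(abs(d - bc_naive(m))), 1e-12)
    }
  })
})

test_that("replicate test separates a fully structured design", {
  # three habitats with identical replicates and mutually disjoint OTUs
  m <- matrix(0L, 3, 6, dimnames = list(paste0("o", 1:3), paste0("s", 1:6)))
  m[1, 1:2] <- 10L; m[2, 3:4] <- 10L; m[3, 5:6] <- 10L
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         habitat_id = rep(c("A", "B", "C"), each = 2))
  res <- replicate_distance_test(bray_curtis(otu_table(m, "bacteria", validate = FALSE)),
                                 meta)
  expect_true(all(res$within == 0))
  expect_true(all(res$between == 1))
  expect_true(res$passed)
  expect_lt(res$p_value, 1e-6)
})

test_that("Welch statistic and p match the closed-form oracle", {
  # hand-built distance matrix: two habitats x two replicates
  within <- c(0.10, 0.12)
  between <- c(0.50, 0.45, 0.55, 0.60)
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d["s1", "s2"] <- within[1];  d["s3", "s4"] <- within[2]
  d["s1", "s3"] <- between[1]; d["s1", "s4"] <- between[2]
  d["s2", "s3"] <- between[3]; d["s2", "s4"] <- between[4]
  d <- d + t(d)
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         habitat_id = c("A", "A", "B", "B"))
  res <- replicate_distance_test(stats::as.dist(d), meta, alpha = 0.05)
  oracle <- welch_oracle(within, between)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-9)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(res$df, oracle$df, tolerance = 1e-9)
  expect_true(res$passed)
})

test_that("type-I error of the replicate test is calibrated under label permutation", {
  # no habitat structure at all: every sample differs by read sampling only,
  # so any relabelling is exchangeable
  sim <- simulate_community(small_spec(seed = 21, block_effect = 1, dispersion = 0,
                                       habitat_sdlog = 0, occupancy = 1))
  dm <- bray_curtis(relative_abundance(sim$tables$bacteria))
  meta <- sim$metadata
  rate <- withr::with_seed(99, {
    mean(replicate(1000, {
      perm <- meta
      perm$habitat_id <- meta$habitat_id[sample.int(nrow(meta))]
      replicate_distance_test(dm, perm, alpha = 0.05)$passed
    }))
  })
  expect_lte(rate, 0.075)   # ~5% nominal plus Monte Carlo slack
})

test_that("pooling sums replicates, conserves reads and detects any-replicate OTUs", {
  sim <- simulate_community(small_spec(seed = 13))
  tbl <- sim$tables$bacteria
  pooled <- pool_replicates(tbl, sim$metadata)
  expect_equal(ncol(as_otu_matrix(pooled)), 21)
  expect_equal(sum(as_otu_matrix(pooled)), sum(as_otu_matrix(tbl)))

  # single-replicate detection: counts (1,0,0) pool to 1
  m <- matrix(c(1L, 0L, 0L), 1, 3, dimnames = list("o1", c("h_r1", "h_r2", "h_r3")))
  meta <- tibble::tibble(sample_id = colnames(m), habitat_id = "h")
  p1 <- pool_replicates(otu_table(m, "bacteria", validate = FALSE), meta)
  expect_equal(unname(as_otu_matrix(p1)[1, 1]), 1)

  # invariant to replicate column order
  shuffled <- tbl[, c("otu_id", rev(sample_ids(tbl)))]
  attr(shuffled, "domain") <- "bacteria"
  class(shuffled) <- class(tbl)
  p2 <- pool_replicates(shuffled, sim$metadata)
  expect_identical(as_otu_matrix(pooled), as_otu_matrix(p2))

  bad_meta <- sim$metadata[-1, ]
  expect_error(pool_replicates(tbl, bad_meta), "missing")
})
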