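test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n_otus = c(bacteria = 10), n_generalists = 6,
                              n_specialists = 6), "exceed")
  expect_error(synthetic_spec(corr_strength = 0), "corr_strength")
  expect_error(synthetic_spec(reads_per_sample = 0), "reads")
  expect_error(synthetic_spec(dispersion = -1), "dispersion")
})

test_that("generation is deterministic given the seed", {
  s1 <- simulate_community(small_spec(seed = 11))
  s2 <- simulate_community(small_spec(seed = 11))
  expect_identical(lapply(s1$tables, as_otu_matrix), lapply(s2$tables, as_otu_matrix))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_community(small_spec(seed = 12))
  expect_false(identical(as_otu_matrix(s1$tables$bacteria),
                         as_otu_matrix(s3$tables$bacteria)))
})

test_that("planted specialists occupy exactly one habitat and never leak", {
  spec <- small_spec(seed = 2, n_specialists = 5)
  ex <- generate_expected_profiles(spec)
  truth <- attr(ex, "truth")
  spc <- truth$otu_id[truth$role == "specialist"]
  expect_length(spc, 5)
  expect_true(all(rowSums(ex[spc, ] > 0) == 1))

  # realized leakage is structurally zero: multinomial keeps zeros at zero
  sim <- simulate_community(spec)
  counts <- do.call(rbind, lapply(sim$tables, as_otu_matrix))
  hab <- sim$metadata$habitat_id[match(colnames(counts), sim$metadata$sample_id)]
  for (id in spc) {
    planted_in <- colnames(ex)[ex[id, ] > 0]
    expect_true(all(counts[id, hab != planted_in] == 0))
  }
})

test_that("each sample holds exactly reads_per_sample reads", {
  sim <- simulate_community(small_spec(seed = 4))
  counts <- do.call(rbind, lapply(sim$tables, as_otu_matrix))
  expect_true(all(colSums(counts) == sim$spec$reads_per_sample))
})

test_that("without block signal the habitat columns are exchangeable", {
  # mean Bray-Curtis within vs between blocks agree when block_effect = 1
  wb <- sapply(1:50, function(s) {
    spec <- small_spec(seed = s, block_effect = 1, n_corr_pairs = 0)
    ex <- generate_expected_profiles(spec)
    d <- as.matrix(vegan::vegdist(t(ex), method = "bray"))
    sites <- sub("-.*$", "", colnames(ex))
    blk <- ifelse(sites %in% c("DH", "CF"), 1, ifelse(sites %in% c("AS", "FL"), 2, 3))
    pair <- which(upper.tri(d), arr.ind = TRUE)
    same <- blk[pair[, 1]] == blk[pair[, 2]]
    c(within = mean(d[pair[same, ]]), between = mean(d[pair[!same, ]]))
  })
  expect_lt(abs(mean(wb["within", ]) - mean(wb["between", ])), 0.02)

  # and with the default block effect the two clearly separate
  spec <- small_spec(seed = 1)
  ex <- generate_expected_profiles(spec)
  d <- as.matrix(vegan::vegdist(t(ex), method = "bray"))
  sites <- sub("-.*$", "", colnames(ex))
  dhcf <- sites %in% c("DH", "CF")
  expect_lt(mean(d[dhcf, dhcf][upper.tri(d[dhcf, dhcf])]),
            mean(d[dhcf, !dhcf]))
})

test_that("planted pairs carry the target rank correlation in expectation", {
  rhos <- sapply(1:60, function(s) {
    spec <- small_spec(seed = s)
    ex <- generate_expected_profiles(spec)
    truth <- attr(ex, "truth")
    sapply(planted_pairs(truth), function(p) {
      cor(rank(ex[p[1], ]), rank(ex[p[2], ]))
    })
  })
  expect_gte(mean(rhos), 0.8)
})

test_that("sample proportions converge to the expected profile at depth", {
  spec <- small_spec(seed = 9, dispersion = 0, reads_per_sample = 1e6,
                     n_replicates = 1)
  sim <- simulate_community(spec)
  counts <- do.call(rbind, lapply(sim$tables, as_otu_matrix))
  hab1 <- sim$metadata$sample_id[1]
  prop <- counts[, hab1] / sum(counts[, hab1])
  exp1 <- sim$expected[rownames(counts), sim$metadata$habitat_id[1]]
  expect_lt(max(abs(prop - exp1)), 0.01)
})

test_that("ground truth stays consistent with the generating spec", {
  spec <- small_spec(seed = 6)
  sim <- simulate_community(spec)
  g <- glance(sim)
  expect_equal(g$n_generalists, spec$n_generalists)
  expect_equal(g$n_specialists, spec$n_specialists)
  expect_equal(g$n_corr_pairs, spec$n_corr_pairs)
  expect_equal(g$n_otus, sum(spec$n_otus))
  expect_true(all(sim$truth$true_occurrence[sim$truth$role == "generalist"] == 21))
  expect_true(all(sim$truth$true_occurrence[sim$truth$role == "specialist"] == 1))
})

test_that("a written community re-reads to the same tables", {
  sim <- simulate_community(small_spec(seed = 8))
  dir <- withr::local_tempdir()
  write_community(sim, dir)
  back <- read_otu_table(file.path(dir, "otu_archaea.tsv"), "archaea")
  orig <- as_otu_matrix(sim$tables$archaea)
  expect_identical(as_otu_matrix(back)[rownames(orig), colnames(orig)], orig)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), 63)
})
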