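test_that("the 1% candidate rule keeps and merges the right OTUs", {
  mk <- function(v, ids) otu_table(matrix(as.integer(v), length(ids), 2,
                                          dimnames = list(ids, c("H1", "H2"))),
                                   "bacteria", validate = FALSE)
  # totals 1000 per habitat: 20/1000 = 2% kept, 9/1000 = 0.9% dropped
  ma <- matrix(c(20L, 5L, 975L, 9L, 9L, 982L), 3, 2,
               dimnames = list(c("hi", "lo", "fill"), c("H1", "H2")))
  ta <- otu_table(ma, "bacteria", validate = FALSE)
  mb <- matrix(c(100L, 900L, 100L, 900L), 2, 2,
               dimnames = list(c("f1", "f2"), c("H1", "H2")))
  tb <- otu_table(mb, "fungi", validate = FALSE)
  merged <- network_candidate_filter(list(bacteria = ta, fungi = tb), 0.01)
  expect_setequal(merged$otu_id, c("hi", "fill", "f1", "f2"))
  expect_equal(nrow(merged),
               nrow(main_otu_filter(ta, 0.01)) + nrow(main_otu_filter(tb, 0.01)))

  tc <- otu_table(matrix(1L, 1, 2, dimnames = list("x", c("H1", "H3"))),
                  "archaea", validate = FALSE)
  expect_error(network_candidate_filter(list(bacteria = ta, archaea = tc)),
               "habitat columns differ")
})

test_that("rho reproduces hand values and the exact permutation p", {
  m <- rbind(up = c(1, 2, 3, 4), mono = c(2, 4, 6, 8),
             down = c(8, 6, 4, 2), mix = c(1, 3, 2, 4))
  colnames(m) <- paste0("h", 1:4)
  tbl <- otu_table(m, "bacteria", validate = FALSE)
  res <- spearman_all_pairs(tbl, method = "exact_perm")
  pick <- function(a, b) res[res$otu_a == a & res$otu_b == b, ]
  expect_equal(pick("up", "mono")$rho, 1)
  expect_equal(pick("up", "down")$rho, -1)
  expect_equal(pick("up", "mix")$rho, 1 - 6 * 2 / (4 * 15))   # 0.8
  expect_equal(pick("up", "mix")$p_value, 4 / 24, tolerance = 1e-12)
})

test_that("t-approximation agrees with cor.test and the exact oracle", {
  withr::with_seed(57, {
    m <- matrix(rpois(10 * 21, 30), 10, 21,
                dimnames = list(paste0("o", 1:10), paste0("h", 1:21)))
    tbl <- otu_table(m, "bacteria", validate = FALSE)
    ours <- spearman_all_pairs(tbl, method = "t_approx")
    for (k in sample(nrow(ours), 10)) {
      ct <- suppressWarnings(
        cor.test(m[ours$otu_a[k], ], m[ours$otu_b[k], ], method = "spearman",
                 exact = FALSE, alternative = "greater"))
      expect_equal(ours$rho[k], unname(ct$estimate), tolerance = 1e-12)
      # p differs only by the lattice-step compensation, tiny at n = 21
      expect_equal(ours$p_value[k], ct$p.value, tolerance = 0.05)
    }
  })
})

test_that("constant profiles are skipped, not propagated", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 5, 3, 4), flat = rep(7, 5))
  colnames(m) <- paste0("h", 1:5)
  expect_message(res <- spearman_all_pairs(otu_table(m, "bacteria", validate = FALSE)),
                 "constant")
  expect_equal(nrow(res), 1)
  expect_false("flat" %in% c(res$otu_a, res$otu_b))
})

test_that("the dual rho/p rule keeps only strong significant positive edges", {
  cors <- tibble::tibble(
    otu_a = c("a", "a", "a"), otu_b = c("b", "c", "d"),
    rho = c(0.7, 0.7, -0.9), p_value = c(1e-4, 0.01, 1e-5), n = 21L)
  net <- edge_selection(cors)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$otu_b, "b")
  expect_setequal(net$nodes$otu_id, c("a", "b"))
  expect_error(edge_selection(cors, rho_min = 2), "rho_min")
  expect_error(edge_selection(cors, alpha = 0), "alpha")

  # relaxing the rho threshold can only add edges
  withr::with_seed(61, {
    rnd <- tibble::tibble(
      otu_a = paste0("o", 1:50), otu_b = paste0("q", 1:50),
      rho = runif(50, -1, 1), p_value = runif(50, 0, 0.01), n = 21L)
    strict <- edge_selection(rnd, rho_min = 0.6, alpha = 0.005)
    loose <- edge_selection(rnd, rho_min = -1, alpha = 0.005)
    key <- function(n) paste(n$edges$otu_a, n$edges$otu_b)
    expect_true(all(key(strict) %in% key(loose)))
  })
})

test_that("degree bookkeeping and global descriptors are exact on small graphs", {
  tri <- tibble::tibble(otu_a = c("a", "a", "b"), otu_b = c("b", "c", "c"),
                        rho = 0.9, p_value = 1e-6, n = 21L)
  net <- edge_selection(tri)
  g <- glance(net)
  expect_equal(g$n_nodes, 3)
  expect_equal(g$n_edges, 3)
  expect_equal(g$mean_degree, 2)          # 2E/N
  expect_equal(g$connectivity_index, 1)   # E/N
  expect_equal(sum(net$nodes$degree), 2 * g$n_edges)

  # path A-B-C with taxa {A,B: T1; C: T2}
  path <- tibble::tibble(otu_a = c("A", "B"), otu_b = c("B", "C"),
                         rho = 0.8, p_value = 1e-6, n = 21L)
  tax <- tibble::tibble(otu_id = c("A", "B", "C"), domain = "bacteria",
                        lineage = c("P;T1", "P;T1", "P;T2"))
  desc <- network_descriptors(edge_selection(path), tax)
  tp <- desc$taxon_pairs
  expect_equal(tp$n_edges[tp$taxon_a == "T1" & tp$taxon_b == "T1"], 1L)
  expect_equal(tp$n_edges[tp$taxon_a == "T1" & tp$taxon_b == "T2"], 1L)
  expect_equal(desc$by_taxon$n_nodes[desc$by_taxon$taxon == "T1"], 2L)

  # empty network reports zeros, not errors
  empty <- edge_selection(tri[0, ])
  expect_equal(glance(empty)$n_nodes, 0)
  desc0 <- network_descriptors(empty, tax)
  expect_equal(nrow(desc0$taxon_pairs), 0)
})

test_that("degree sum equals twice the edge count on simulated networks", {
  sim <- simulate_community(small_spec(seed = 47))
  pooled <- lapply(sim$tables, pool_replicates, meta = sim$metadata)
  net <- build_network(pooled)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  expect_true(all(net$edges$rho > 0.6))
  expect_true(all(net$edges$p_value < 0.001))
  # every endpoint is a node
  expect_true(all(c(net$edges$otu_a, net$edges$otu_b) %in% net$nodes$otu_id))
})

test_that("graphml export carries domain and degree attributes", {
  sim <- simulate_community(small_spec(seed = 53))
  pooled <- lapply(sim$tables, pool_replicates, meta = sim$metadata)
  net <- build_network(pooled)
  expect_gt(nrow(net$edges), 0)   # planted pairs guarantee edges
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::vertex_attr_names(g),
                  c("name", "domain", "degree", "id"))
  expect_true("rho" %in% igraph::edge_attr_names(g))
})
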