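#' Configure a full gradient-analysis run
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' standard procedure: replicate QC at alpha 0.001, main-OTU cut 1 per
#' mille, network candidate cut 1%, edge rule rho > 0.6 and p < 0.001,
#' generalist rule >= 16 of 21 habitats, detection at >= 1 pooled read.
#' Exactly one of `input` (paths) or `synthetic` (a [synthetic_spec()])
#' must be given.
#'
#' @param input List with `otu_tables` (named paths per domain),
#'   `metadata`, `taxonomy`, or `NULL`.
#' @param synthetic A [synthetic_spec()], or `NULL`.
#' @param out_dir Output directory.
#' @param main_otu,network,rho_min,alpha,generalist_min,qc_alpha,min_count
#'   Thresholds (see above).
#' @param weight_domains Equal-weight domains in habitat clustering.
#' @param keep_isolated Keep edge-less candidate OTUs as network nodes.
#' @param p_method Spearman p engine (`"t_approx"` or `"exact_perm"`).
#' @param bh_correct Apply Benjamini-Hochberg to the edge p-values before
#'   thresholding (off by default: the standard procedure applies none;
#'   either way the choice is logged).
#' @param force Continue even if replicate QC fails.
#' @param seed Seed recorded in the manifest (drives synthetic generation).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, out_dir = tempfile("run"),
                            main_otu = 0.001, network = 0.01, rho_min = 0.6,
                            alpha = 0.001, generalist_min = 16, qc_alpha = 0.001,
                            min_count = 1, weight_domains = TRUE,
                            keep_isolated = FALSE, p_method = "t_approx",
                            bh_correct = FALSE, force = FALSE, seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    stop("give exactly one of 'input' or 'synthetic'", call. = FALSE)
  }
  stopifnot(main_otu > 0, main_otu < 1, network > 0, network < 1,
            alpha > 0, alpha < 1, qc_alpha > 0, qc_alpha < 1,
            rho_min >= -1, rho_min <= 1, generalist_min > 1, min_count >= 1)
  cfg <- list(input = input, synthetic = synthetic, out_dir = out_dir,
              main_otu = main_otu, network = network, rho_min = rho_min,
              alpha = alpha, generalist_min = generalist_min,
              qc_alpha = qc_alpha, min_count = min_count,
              weight_domains = weight_domains, keep_isolated = keep_isolated,
              p_method = p_method, bh_correct = bh_correct, force = force,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (a `synthetic` mapping is passed to [synthetic_spec()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_spec, y$synthetic)
  do.call(pipeline_config, y)
}

#' Run the full gradient analysis
#'
#' Executes replicate QC, pooling, main-OTU filtering, habitat clustering,
#' breadth classification and co-occurrence network inference, writing all
#' products to `cfg$out_dir` in canonical (byte-reproducible) order along
#' with a run manifest. A failed replicate QC halts the run unless
#' `cfg$force` is set.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return The manifest (invisibly also written as `manifest.yaml`): config
#'   hash inputs, seed, per-stage counts, QC and network summaries.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$synthetic)) {
    cfg$synthetic$seed <- cfg$seed
    say("stage simulate: seed ", cfg$seed)
    sim <- simulate_community(cfg$synthetic)
    tables <- sim$tables; meta <- sim$metadata; tax <- sim$taxonomy
    write_community(sim, file.path(cfg$out_dir, "synthetic"))
  } else {
    tables <- purrr::imap(cfg$input$otu_tables, ~ read_otu_table(.x, .y))
    meta <- read_sample_metadata(cfg$input$metadata)
    tax <- read_taxonomy(cfg$input$taxonomy)
  }

  say("stage qc: replicate distance test per domain at alpha ", cfg$qc_alpha)
  qc <- lapply(tables, function(t) {
    replicate_distance_test(bray_curtis(relative_abundance(t)), meta, cfg$qc_alpha)
  })
  qc_pass <- all(vapply(qc, `[[`, logical(1), "passed"))
  if (!qc_pass && !cfg$force) {
    stop("replicate QC failed (replicates not more similar than non-replicates); ",
         "rerun with force = TRUE to pool anyway", call. = FALSE)
  }

  say("stage pool: summing replicates per habitat")
  pooled <- lapply(tables, pool_replicates, meta = meta)

  say("stage main-otu filter: relative abundance > ", cfg$main_otu)
  main <- lapply(pooled, main_otu_filter, threshold = cfg$main_otu)

  say("stage cluster: Bray-Curtis UPGMA over habitats (equal domain weights: ",
      cfg$weight_domains, ")")
  dendro <- cluster_habitats(main, weight_domains = cfg$weight_domains)
  write_dendrogram(dendro, file.path(cfg$out_dir, "habitat_dendrogram.nwk"))
  taxa_long <- dplyr::bind_rows(lapply(main, taxon_aggregate, tax = tax, rank = "class"))
  write_long_table(taxa_long, file.path(cfg$out_dir, "taxon_abundance.tsv"))

  say("stage breadth: generalist >= ", cfg$generalist_min,
      " habitats, specialist = 1, detection >= ", cfg$min_count, " read(s)")
  n_hab <- length(unique(meta$habitat_id))
  breadth <- lapply(pooled, function(t) {
    classify_breadth(occurrence_profile(t, cfg$min_count),
                     n_habitats = n_hab, generalist_min = cfg$generalist_min)
  })
  breadth_long <- dplyr::bind_rows(purrr::map2(breadth, pooled, breadth_summary,
                                               tax = tax, min_count = cfg$min_count))
  write_long_table(breadth_long, file.path(cfg$out_dir, "breadth_summary.tsv"))
  class_tbl <- dplyr::bind_rows(purrr::imap(breadth, ~ tibble::tibble(
    otu_id = .x$otu_id, domain = .y, occurrence = .x$occurrence,
    breadth_class = as.character(.x$breadth_class))))
  write_long_table(class_tbl, file.path(cfg$out_dir, "breadth_classes.tsv"))

  say("stage network: candidates > ", cfg$network, ", edges rho > ", cfg$rho_min,
      " & p < ", cfg$alpha, " (", cfg$p_method, ", BH correction: ",
      cfg$bh_correct, ")")
  cand <- network_candidate_filter(pooled, cfg$network)
  cors <- spearman_all_pairs(cand, method = cfg$p_method)
  if (cfg$bh_correct) cors$p_value <- stats::p.adjust(cors$p_value, "BH")
  net <- edge_selection(cors, rho_min = cfg$rho_min, alpha = cfg$alpha,
                        nodes = cand[, c("otu_id", "domain")],
                        keep_isolated = cfg$keep_isolated)
  write_network(net, file.path(cfg$out_dir, "network.graphml"), "graphml")
  write_network(net, file.path(cfg$out_dir, "network_edges.tsv"), "edgelist")
  desc <- network_descriptors(net, tax)
  write_long_table(desc$by_taxon, file.path(cfg$out_dir, "network_taxa.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("biomebridge")),
    seed = cfg$seed,
    thresholds = cfg[c("main_otu", "network", "rho_min", "alpha",
                       "generalist_min", "qc_alpha", "min_count")],
    flags = cfg[c("weight_domains", "keep_isolated", "p_method", "bh_correct")],
    stages = list(
      samples_in = length(unique(meta$sample_id)),
      habitats = n_hab,
      otus_in = vapply(tables, nrow, integer(1)),
      qc = lapply(qc, function(q) list(t = q$statistic, p = q$p_value,
                                       passed = q$passed)),
      main_otus = vapply(main, nrow, integer(1)),
      breadth = lapply(breadth, function(b) as.list(table(b$breadth_class))),
      network_candidates = nrow(cand),
      network = as.list(glance(net)[c("n_nodes", "n_edges",
                                      "connectivity_index", "mean_degree")])
    )
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, qc = qc, pooled = pooled, dendro = dendro,
                 breadth = breadth, network = net, descriptors = desc))
}
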