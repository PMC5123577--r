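#' The 21-habitat terrestrial-freshwater sampling design
#'
#' Five soil sites (DH, CF, FL with three depth layers; AS with two), a
#' five-layer shore profile (SH), three lake-water depths (LA) and two
#' sediment stations (SE): 21 habitats, each sampled in replicate.
#'
#' @param n_replicates Field replicates per habitat (default 3).
#' @return Sample metadata tibble: `sample_id`, `site_code`, `layer_label`,
#'   `biome_class`, `replicate_index`, `habitat_id`.
#' @export
study_design <- function(n_replicates = 3) {
  habs <- tibble::tibble(
    site_code = c(rep("DH", 3), rep("CF", 3), rep("FL", 3), rep("AS", 2),
                  rep("SH", 5), rep("LA", 3), rep("SE", 2)),
    layer_label = c("Top", "Med", "Low", "Top", "Med", "Low", "Top", "Med", "Low",
                    "Top", "Low", as.character(1:5), as.character(1:3), "Top", "Low"),
    biome_class = c(rep("soil", 11), rep("shore", 5), rep("freshwater", 3),
                    rep("sediment", 2))
  )
  meta <- tidyr::crossing(habs, replicate_index = seq_len(n_replicates))
  meta <- derive_habitat(meta)
  meta$sample_id <- sprintf("%s_r%d", meta$habitat_id, meta$replicate_index)
  meta <- meta[order(match(meta$habitat_id, unique(derive_habitat(habs)$habitat_id)),
                     meta$replicate_index), ]
  validate_metadata(meta[, c("sample_id", "site_code", "layer_label",
                             "biome_class", "replicate_index", "habitat_id")])
}

#' Specify a synthetic microbial community
#'
#' Defines the generative model for OTU count tables with the structure the
#' downstream analysis assumes: log-normal species abundances, habitat
#' occupancy (planted generalists present everywhere, specialists in exactly
#' one habitat), multiplicative enrichment of OTUs inside their preferred
#' habitat block, latent-factor correlated OTU pairs, Dirichlet replicate
#' overdispersion and multinomial read sampling. Planted OTUs draw their
#' base abundance from the upper tail of the species abundance distribution
#' (generalists > specialists > pair members > background) so they occupy
#' the detectable range that breadth and network figures describe.
#'
#' @param n_replicates Replicates per habitat (3).
#' @param reads_per_sample Sequencing depth per replicate sample (5000).
#' @param n_otus Named integer vector of OTUs per domain.
#' @param n_generalists OTUs planted with non-zero expectation in every habitat.
#' @param n_specialists OTUs planted in exactly one habitat.
#' @param habitat_blocks Partition of sites into similarity blocks.
#' @param block_effect Multiplicative in-block enrichment (1 = no block signal).
#' @param n_corr_pairs OTU pairs sharing a latent abundance driver.
#' @param corr_strength Target Spearman correlation of planted pairs, in (0, 1].
#' @param dispersion Dirichlet overdispersion of replicate proportions
#'   (0 = replicates reproduce the habitat expectation exactly; the
#'   per-replicate coefficient of variation of an OTU at proportion p is
#'   about sqrt(dispersion/p)).
#' @param occupancy Per-habitat presence probability for unplanted OTUs.
#' @param base_sdlog Log-sd of the species abundance distribution.
#' @param planted_sdlog Log-sd of planted (generalist/specialist/pair) base
#'   abundances; tighter than `base_sdlog` so planted OTUs sit in the
#'   detectable range the breadth figures of gradient surveys describe.
#' @param habitat_sdlog Log-sd of per-habitat abundance variation.
#' @param seed Integer RNG seed governing all draws.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_replicates = 3,
                           reads_per_sample = 5000,
                           n_otus = c(bacteria = 300, fungi = 120, archaea = 80),
                           n_generalists = 10,
                           n_specialists = 60,
                           habitat_blocks = list(c("DH", "CF"), c("AS", "FL"),
                                                 c("SH", "LA", "SE")),
                           block_effect = 8,
                           n_corr_pairs = 10,
                           corr_strength = 0.9,
                           dispersion = 0.002,
                           occupancy = 0.4,
                           base_sdlog = 1.5,
                           planted_sdlog = 0.5,
                           habitat_sdlog = 0.5,
                           seed = 1L) {
  n_otus <- unlist(n_otus)   # tolerate YAML-parsed lists
  spec <- list(n_replicates = as.integer(n_replicates),
               reads_per_sample = as.integer(reads_per_sample),
               n_otus = n_otus, n_generalists = as.integer(n_generalists),
               n_specialists = as.integer(n_specialists),
               habitat_blocks = habitat_blocks, block_effect = block_effect,
               n_corr_pairs = as.integer(n_corr_pairs),
               corr_strength = corr_strength, dispersion = dispersion,
               occupancy = occupancy, base_sdlog = base_sdlog,
               planted_sdlog = planted_sdlog, habitat_sdlog = habitat_sdlog,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (is.null(names(spec$n_otus)) || any(!nzchar(names(spec$n_otus)))) {
    stop("n_otus must be a named per-domain vector", call. = FALSE)
  }
  n <- sum(spec$n_otus)
  if (spec$n_generalists + spec$n_specialists + 2L * spec$n_corr_pairs > n) {
    stop("planted OTUs exceed n_otus", call. = FALSE)
  }
  if (spec$corr_strength <= 0 || spec$corr_strength > 1) {
    stop("corr_strength must be in (0, 1]", call. = FALSE)
  }
  if (spec$reads_per_sample <= 0) stop("reads_per_sample must be positive", call. = FALSE)
  if (spec$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (spec$occupancy <= 0 || spec$occupancy > 1) stop("occupancy must be in (0, 1]", call. = FALSE)
  if (spec$block_effect < 1) stop("block_effect must be >= 1", call. = FALSE)
  invisible(spec)
}

otu_prefix <- c(bacteria = "bac", fungi = "fun", archaea = "arc")

#' Expected relative-abundance profiles (OTU x habitat)
#'
#' Draws the deterministic layer of the generative model: base abundances
#' from a log-normal species abundance distribution (planted generalists and
#' correlated pairs from a higher mean so they are detectable, as the
#' detectable taxa in gradient surveys are), presence masks, block
#' enrichment, and the shared latent factor of each planted pair scaled so
#' the pair's expected-profile Spearman correlation matches `corr_strength`
#' (via the Gaussian-copula relation rank-rho = (6/pi) asin(r/2)). Habitat
#' columns are renormalised to sum to one.
#'
#' @param spec A [synthetic_spec()].
#' @return Numeric matrix (OTU x habitat) with attributes `truth`
#'   (per-OTU role/occurrence tibble) and `design` (habitat order).
#' @export
generate_expected_profiles <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_expected_profiles_impl(spec))
}

generate_expected_profiles_impl <- function(spec) {
  design <- study_design(1)
  habitats <- design$habitat_id
  H <- length(habitats)
  domains <- rep(names(spec$n_otus), spec$n_otus)
  n <- length(domains)
  ids <- sprintf("%s_%04d", otu_prefix[domains], stats::ave(seq_len(n), domains, FUN = seq_along))

  role <- rep("background", n)
  planted <- sample.int(n, spec$n_generalists + spec$n_specialists + 2L * spec$n_corr_pairs)
  i_gen  <- planted[seq_len(spec$n_generalists)]
  i_spec <- planted[spec$n_generalists + seq_len(spec$n_specialists)]
  i_pair <- planted[spec$n_generalists + spec$n_specialists +
                    seq_len(2L * spec$n_corr_pairs)]
  role[i_gen] <- "generalist"; role[i_spec] <- "specialist"; role[i_pair] <- "corr_pair"
  pair_id <- rep(NA_integer_, n)
  if (spec$n_corr_pairs > 0) pair_id[i_pair] <- rep(seq_len(spec$n_corr_pairs), each = 2)

  meanlog <- rep(0, n)
  meanlog[i_pair] <- 2.5
  meanlog[i_spec] <- 3
  meanlog[i_gen] <- 4
  sdlog <- ifelse(role == "background", spec$base_sdlog, spec$planted_sdlog)
  base <- stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)

  mask <- matrix(stats::runif(n * H) < spec$occupancy, n, H)
  none <- which(rowSums(mask) == 0)
  if (length(none)) mask[cbind(none, sample.int(H, length(none), replace = TRUE))] <- TRUE
  mask[c(i_gen, i_pair), ] <- TRUE
  mask[i_spec, ] <- FALSE
  mask[cbind(i_spec, sample.int(H, length(i_spec), replace = TRUE))] <- TRUE

  sites <- sub("-.*$", "", habitats)
  block_of_site <- rep(NA_integer_, length(sites))
  for (b in seq_along(spec$habitat_blocks)) {
    block_of_site[sites %in% spec$habitat_blocks[[b]]] <- b
  }
  block_of_site[is.na(block_of_site)] <- 0L  # sites outside every block: no enrichment
  blk_sizes <- vapply(seq_along(spec$habitat_blocks),
                      function(b) sum(block_of_site == b, na.rm = TRUE), numeric(1))
  blk <- sample.int(length(spec$habitat_blocks), n, replace = TRUE,
                    prob = blk_sizes / sum(blk_sizes))
  if (spec$n_corr_pairs > 0) {   # pair members share a preferred block
    blk[i_pair[seq_along(i_pair) %% 2 == 0]] <- blk[i_pair[seq_along(i_pair) %% 2 == 1]]
  }
  mult <- 1 + (spec$block_effect - 1) * outer(blk, block_of_site, "==")

  z <- matrix(stats::rnorm(n * H), n, H)
  if (spec$n_corr_pairs > 0) {
    a <- sqrt(2 * sin(pi * spec$corr_strength / 6))  # latent loading for target rank-rho
    for (p in seq_len(spec$n_corr_pairs)) {
      u <- stats::rnorm(H)
      for (i in i_pair[pair_id[i_pair] == p]) {
        z[i, ] <- a * u + sqrt(1 - a^2) * z[i, ]
      }
    }
  }
  expected <- base * exp(spec$habitat_sdlog * z) * mult * mask
  tot <- colSums(expected)
  if (any(tot == 0)) stop("habitat column with zero total expectation", call. = FALSE)
  expected <- sweep(expected, 2, tot, "/")
  dimnames(expected) <- list(ids, habitats)

  attr(expected, "truth") <- tibble::tibble(
    otu_id = ids, domain = domains, role = role, pair_id = pair_id,
    block = blk, true_occurrence = rowSums(mask)
  )
  attr(expected, "design") <- habitats
  expected
}

#' Sample replicate-level OTU count tables from expected profiles
#'
#' For each habitat x replicate, proportions are perturbed with a Dirichlet
#' draw of concentration `expected / dispersion` (structural zeros stay
#' zero; `dispersion = 0` reproduces the expectation exactly) and
#' `reads_per_sample` reads are drawn multinomially. Deterministic given the
#' spec's seed.
#'
#' @param expected Expected profile matrix from [generate_expected_profiles()].
#' @param spec The same [synthetic_spec()].
#' @return List: `tables` (per-domain `otu_tbl`s over the replicate
#'   samples), `metadata`, `taxonomy` (synthetic lineages), `truth`.
#' @export
sample_counts <- function(expected, spec) {
  tot <- colSums(expected)
  if (any(tot == 0)) stop("habitat column with zero total expectation", call. = FALSE)
  if (any(abs(tot - 1) > 1e-8)) stop("expected profile columns must sum to 1", call. = FALSE)
  withr::with_seed(spec$seed + 1L, sample_counts_impl(expected, spec))
}

sample_counts_impl <- function(expected, spec) {
  truth <- attr(expected, "truth")
  meta <- study_design(spec$n_replicates)
  n <- nrow(expected)
  counts <- matrix(0L, n, nrow(meta), dimnames = list(rownames(expected), meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    p <- expected[, meta$habitat_id[s]]
    if (spec$dispersion > 0) {
      g <- stats::rgamma(n, shape = p / spec$dispersion)
      p <- g / sum(g)
    }
    counts[, s] <- stats::rmultinom(1, spec$reads_per_sample, p)
  }
  tables <- lapply(stats::setNames(nm = unique(truth$domain)), function(d) {
    otu_table(counts[truth$domain == d, , drop = FALSE], d)
  })
  list(tables = tables, metadata = meta,
       taxonomy = synthetic_taxonomy(truth), truth = truth)
}

lineage_pool <- list(
  bacteria = c("Actinobacteria;Actinomycetia", "Proteobacteria;Alphaproteobacteria",
               "Proteobacteria;Gammaproteobacteria", "Acidobacteria;Acidobacteriia",
               "Bacteroidetes;Bacteroidia", "Firmicutes;Bacilli",
               "Verrucomicrobia;Verrucomicrobiae", "Chloroflexi;Anaerolineae",
               "Cyanobacteria;Cyanophyceae", "unclassified"),
  fungi = c("Ascomycota;Sordariomycetes", "Ascomycota;Dothideomycetes",
            "Ascomycota;Leotiomycetes", "Basidiomycota;Agaricomycetes",
            "Basidiomycota;Tremellomycetes", "unclassified"),
  archaea = c("Thaumarchaeota;Nitrososphaerales", "Euryarchaeota;Methanosarcinales",
              "Euryarchaeota;Methanobacteriales", "Euryarchaeota;Thermoplasmatales",
              "unclassified")
)

synthetic_taxonomy <- function(truth) {
  lineage <- vapply(seq_len(nrow(truth)), function(i) {
    pool <- lineage_pool[[truth$domain[i]]]
    sample(pool, 1)
  }, character(1))
  tibble::tibble(otu_id = truth$otu_id, domain = truth$domain, lineage = lineage)
}

#' Simulate a full synthetic community
#'
#' Runs [generate_expected_profiles()] then [sample_counts()] under the
#' spec's seed (per-stage substreams are derived from it), returning
#' everything downstream stages and ground-truth comparisons need.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A `synthetic_community`: list with `tables` (named list of
#'   per-domain `otu_tbl`s), `metadata`, `taxonomy`, `truth`, `expected`,
#'   `spec`.
#' @examples
#' sim <- simulate_community(synthetic_spec(n_otus = c(bacteria = 40, fungi = 20,
#'                                                     archaea = 10),
#'                                          n_specialists = 6, seed = 7))
#' names(sim$tables)
#' @export
simulate_community <- function(spec, seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  expected <- generate_expected_profiles(spec)
  out <- sample_counts(expected, spec)
  out$expected <- expected
  out$spec <- spec
  class(out) <- "synthetic_community"
  out
}

#' Write a simulated community to a directory
#'
#' Writes per-domain OTU TSVs (`otu_<domain>.tsv`), `metadata.tsv`,
#' `taxonomy.tsv` and `ground_truth.tsv` in canonical ordering.
#'
#' @param sim A `synthetic_community`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(sim$tables)) {
    write_otu_table(sim$tables[[d]], file.path(dir, paste0("otu_", d, ".tsv")))
  }
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(sim$truth[order(sim$truth$otu_id), ],
                   file.path(dir, "ground_truth.tsv"), progress = FALSE)
  invisible(dir)
}
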