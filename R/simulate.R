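# Synthetic-data generator emulating the 2-genotype x 2-treatment x
# 3-timepoint x 3-replicate log2-intensity microarray design, with planted
# treatment effects following temporal profiles (optionally lagged in the
# second genotype), planted correlation modules with anti-correlated
# switch nodes, and a planted enriched term. Ground truth accompanies
# every dataset so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 2 genotypes (MP, SG) x
#' treatments WW/WS x 3 timepoints x 3 replicates, per-gene log2 baselines
#' `N(8, 1.5^2)`, additive replicate noise `N(0, 0.25^2)`, and planted
#' WS - WW offsets of up to 2 log2 units following integer temporal
#' profiles. The lag option delays every planted profile by one timepoint
#' in the second genotype, recreating a delayed-responder genotype.
#'
#' @param n_genes number of genes (default 2000; the emulated array scale
#'   would be 29000).
#' @param n_timepoints observed timepoints (default 3).
#' @param n_replicates replicates per cell (default 3).
#' @param genotypes two genotype labels (default `c("MP", "SG")`).
#' @param baseline_mean,baseline_sd per-gene baseline distribution, log2
#'   units (defaults 8.0, 1.5).
#' @param noise_sd within-replicate additive Gaussian sd, log2 units
#'   (default 0.25).
#' @param de_fraction fraction of genes carrying a treatment effect
#'   (default 0.1).
#' @param effect_size_log2 planted peak `|WS - WW|` offset for DE genes
#'   (default 2.0).
#' @param profile_catalog named list of integer temporal profiles (one
#'   level per observed timepoint); planted offsets are
#'   `effect_size_log2 * level / max|level|`. DE genes are split equally
#'   across profiles unless `profile_counts` is given.
#' @param profile_counts optional named integer vector of genes per
#'   profile (overrides the equal split; the sum defines the DE count).
#' @param genotype_lag delay planted profiles by one timepoint in the
#'   second genotype (default `TRUE`).
#' @param module_spec list of `list(size, r)` planted correlation modules
#'   (sizes `>= 5`, intra-module Pearson target `r < 1`).
#' @param n_switch planted anti-correlated bridge genes (default 2).
#' @param enriched_term_spec `list(size, de_overlap)` for the planted
#'   enriched term.
#' @param n_background_terms random background terms (default 30).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_timepoints = 3,
                              n_replicates = 3,
                              genotypes = c("MP", "SG"),
                              baseline_mean = 8.0, baseline_sd = 1.5,
                              noise_sd = 0.25, de_fraction = 0.1,
                              effect_size_log2 = 2.0,
                              profile_catalog = NULL,
                              profile_counts = NULL,
                              genotype_lag = TRUE,
                              module_spec = list(list(size = 25, r = 0.9),
                                                 list(size = 25, r = 0.9)),
                              n_switch = 2,
                              enriched_term_spec = list(size = 40,
                                                        de_overlap = 30),
                              n_background_terms = 30,
                              seed = 1) {
  if (is.null(profile_catalog)) {
    T <- n_timepoints
    ramp <- function(v) v[seq_len(T)]
    profile_catalog <- list(
      up_sustained   = ramp(c(1, 1, 1, 1, 1)),
      up_late        = ramp(c(0, rep(0, max(0, T - 2)), 1))[seq_len(T)],
      up_ramp        = ramp(seq_len(5))[seq_len(T)],
      down_sustained = -ramp(c(1, 1, 1, 1, 1)),
      transient      = { v <- rep(0, T); v[ceiling(T / 2)] <- 1; v }
    )
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              genotypes = genotypes,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, de_fraction = de_fraction,
              effect_size_log2 = effect_size_log2,
              profile_catalog = profile_catalog,
              profile_counts = profile_counts,
              genotype_lag = isTRUE(genotype_lag),
              module_spec = module_spec, n_switch = as.integer(n_switch),
              enriched_term_spec = enriched_term_spec,
              n_background_terms = as.integer(n_background_terms),
              seed = as.integer(seed))
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (cfg$effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (length(cfg$genotypes) != 2) stop("exactly 2 genotypes are required")
  if (any(lengths(cfg$profile_catalog) != cfg$n_timepoints))
    stop("every profile must have one level per timepoint")
  for (ms in cfg$module_spec) {
    if (ms$size < 5) stop("module sizes must be >= 5")
    if (ms$r >= 1) stop("intra-module correlation target must be < 1")
  }
  if (!is.null(cfg$profile_counts) &&
      sum(cfg$profile_counts) > cfg$n_genes)
    stop("profile_counts ask for more genes than n_genes")
  structure(cfg, class = "simulation_config")
}

# Decorrelate RNG streams of the generator's components: two components
# seeded from the same base must not replay each other's sample() picks.
mix_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 279470273 + salt * 4294957665) %%
               2147483629)
}

# Planted WS - WW offset for one profile at each timepoint, for each
# genotype (second genotype optionally lagged by one timepoint).
profile_offsets <- function(levels, effect, lag) {
  peak <- max(abs(levels))
  base <- if (peak > 0) effect * levels / peak else levels * 0
  lagged <- if (lag) c(0, base[-length(base)]) else base
  list(base, lagged)
}

#' Simulate a full water-stress expression experiment
#'
#' Generates log2 intensities for the configured design. DE genes receive
#' their profile's WS - WW offset on the WS samples (lagged one timepoint
#' in the second genotype when configured); non-DE genes share means
#' across treatments; all replicates get additive Gaussian noise.
#'
#' @param config a [simulation_config()].
#' @return list with `experiment` (a [ws_experiment]) and `truth` (list:
#'   `de_genes`, `profile` named vector, `offsets` per-genotype list of
#'   per-profile offset vectors).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(mix_seed(config$seed, 0))
  G <- config$n_genes
  T <- config$n_timepoints
  R <- config$n_replicates
  gts <- config$genotypes
  design <- expand.grid(replicate = seq_len(R),
                        timepoint = seq_len(T) - 1L,
                        treatment = c("WW", "WS"),
                        genotype = gts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "timepoint", "replicate")]
  design$sample_id <- sprintf("%s_%s_T%d_R%d", design$genotype,
                              design$treatment, design$timepoint,
                              design$replicate)
  gene_ids <- sprintf("GENE_%05d", seq_len(G))

  counts <- config$profile_counts
  if (is.null(counts)) {
    n_de <- round(config$de_fraction * G)
    np <- length(config$profile_catalog)
    counts <- stats::setNames(
      diff(floor(seq(0, n_de, length.out = np + 1))),
      names(config$profile_catalog))
  }
  if (sum(counts) > G) stop("profile counts exceed n_genes")
  de_genes <- if (sum(counts) > 0) sample(gene_ids, sum(counts)) else
    character(0)
  profile_of <- stats::setNames(rep(names(counts), counts), de_genes)

  offsets <- lapply(config$profile_catalog, profile_offsets,
                    effect = config$effect_size_log2,
                    lag = config$genotype_lag)

  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  vals <- matrix(stats::rnorm(G * nrow(design), 0, config$noise_sd),
                 G, nrow(design)) + baseline
  dimnames(vals) <- list(gene_ids, design$sample_id)
  if (length(de_genes)) {
    ws_cols <- which(design$treatment == "WS")
    for (col in ws_cols) {
      gt_idx <- match(design$genotype[col], gts)
      tp <- design$timepoint[col] + 1L
      add <- vapply(profile_of, function(p) offsets[[p]][[gt_idx]][tp],
                    numeric(1))
      vals[de_genes, col] <- vals[de_genes, col] + add
    }
  }
  truth <- list(de_genes = sort(de_genes), profile = profile_of,
                offsets = offsets)
  list(experiment = ws_experiment(vals, design), truth = truth)
}

#' Plant correlation modules and switch nodes
#'
#' Module members are a shared latent sample profile plus Gaussian noise
#' scaled so the intra-module Pearson correlation approximates the target
#' (`noise var = 1/r - 1` for a unit-variance latent). Each switch gene is
#' the negated, renormalized sum of two module latents plus a small noise
#' term, so its correlations to both modules' members are strongly
#' negative and it bridges them above any moderate threshold.
#'
#' @param config a [simulation_config()] (uses `module_spec`, `n_switch`,
#'   design fields and `seed`).
#' @return list with `experiment` (a [ws_experiment] restricted to the
#'   planted genes) and `truth` (list: `modules` named vector of module
#'   ids, `switch_genes`, `switch_bridges` list of bridged module pairs).
#' @export
plant_network_structure <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!length(config$module_spec)) stop("module_spec must be nonempty")
  set.seed(mix_seed(config$seed, 1))
  T <- config$n_timepoints; R <- config$n_replicates
  design <- expand.grid(replicate = seq_len(R),
                        timepoint = seq_len(T) - 1L,
                        treatment = c("WW", "WS"),
                        genotype = config$genotypes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "timepoint", "replicate")]
  design$sample_id <- sprintf("%s_%s_T%d_R%d", design$genotype,
                              design$treatment, design$timepoint,
                              design$replicate)
  S <- nrow(design)
  M <- length(config$module_spec)
  latents <- lapply(seq_len(M), function(m) {
    l <- stats::rnorm(S)
    (l - mean(l)) / stats::sd(l)
  })
  rows <- list(); ids <- character(0)
  modules <- integer(0)
  for (m in seq_len(M)) {
    ms <- config$module_spec[[m]]
    sigma <- sqrt(1 / ms$r - 1)
    block <- t(vapply(seq_len(ms$size), function(i)
      8 + latents[[m]] + sigma * stats::rnorm(S), numeric(S)))
    rownames(block) <- sprintf("MOD%d_%03d", m, seq_len(ms$size))
    rows[[length(rows) + 1]] <- block
    modules <- c(modules,
                 stats::setNames(rep(m, ms$size), rownames(block)))
  }
  switch_ids <- character(0)
  bridges <- list()
  if (config$n_switch > 0) {
    if (M < 2) stop("switch genes require at least 2 modules")
    pairs <- utils::combn(M, 2)
    sw <- t(vapply(seq_len(config$n_switch), function(k) {
      pr <- pairs[, ((k - 1) %% ncol(pairs)) + 1]
      bridges[[k]] <<- pr
      lat <- -(latents[[pr[1]]] + latents[[pr[2]]]) / sqrt(2)
      8 + lat + 0.2 * stats::rnorm(S)
    }, numeric(S)))
    switch_ids <- sprintf("SWITCH_%02d", seq_len(config$n_switch))
    rownames(sw) <- switch_ids
    rows[[length(rows) + 1]] <- sw
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- design$sample_id
  truth <- list(modules = modules, switch_genes = switch_ids,
                switch_bridges = bridges)
  list(experiment = ws_experiment(vals, design), truth = truth)
}

#' Plant a term map with one enriched term
#'
#' One term overlaps the DE set far above hypergeometric expectation;
#' background terms are uniform random gene sets of the same size.
#'
#' @param genes full gene universe.
#' @param de_genes the planted DE set the term should overlap.
#' @param enriched_term_spec `list(size, de_overlap)`; `size >= 1`,
#'   `de_overlap <= min(size, |de_genes|)`.
#' @param n_background_terms number of random background terms.
#' @param seed RNG seed.
#' @return list with `term_map` (named list) and `truth` (list:
#'   `enriched_term`, `members`).
#' @export
plant_enrichment <- function(genes, de_genes, enriched_term_spec,
                             n_background_terms = 30, seed = 1) {
  size <- enriched_term_spec$size
  overlap <- enriched_term_spec$de_overlap
  if (is.null(size) || size < 1) stop("term size must be >= 1")
  if (size > length(genes)) stop("term size exceeds gene universe")
  if (overlap > min(size, length(de_genes)))
    stop("de_overlap exceeds term size or DE set size")
  set.seed(mix_seed(seed, 2))
  planted <- c(sample(de_genes, overlap),
               sample(setdiff(genes, de_genes), size - overlap))
  term_map <- list(TERM_PLANTED = sort(planted))
  if (n_background_terms > 0) {
    bg <- lapply(seq_len(n_background_terms), function(i)
      sort(sample(genes, size)))
    names(bg) <- sprintf("BG_%03d", seq_len(n_background_terms))
    term_map <- c(term_map, bg)
  }
  list(term_map = term_map,
       truth = list(enriched_term = "TERM_PLANTED",
                    members = sort(planted)))
}

#' Write simulation ground truth as JSON
#'
#' @param truth truth list from a simulator function.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
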