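# Shared fixture builders and small independent oracles.

# Minimal sample sheet: genotypes x treatments x timepoints x replicates.
make_design <- function(genotypes = "MP", treatments = c("WW", "WS"),
                        n_timepoints = 1, n_replicates = 2) {
  d <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint = seq_len(n_timepoints) - 1L,
                   treatment = treatments, genotype = genotypes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("genotype", "treatment", "timepoint", "replicate")]
  d$sample_id <- sprintf("%s_%s_T%d_R%d", d$genotype, d$treatment,
                         d$timepoint, d$replicate)
  d
}

# Deterministic experiment from an explicit matrix.
make_experiment <- function(values, design) {
  ws_experiment(values, design)
}

# Experiment where every (genotype, treatment, timepoint) cell has the
# given per-gene means, with replicates jittered by `noise` (0 = exact).
make_cell_experiment <- function(cell_means, design, noise = 0, seed = 1) {
  set.seed(seed)
  genes <- rownames(cell_means)
  vals <- sapply(seq_len(nrow(design)), function(i) {
    cell <- paste(design$genotype[i], design$treatment[i],
                  design$timepoint[i], sep = ".")
    cell_means[, cell] + if (noise > 0) rnorm(length(genes), 0, noise) else 0
  })
  dimnames(vals) <- list(genes, design$sample_id)
  ws_experiment(vals, design)
}

f1_score <- function(found, truth) {
  tp <- length(intersect(found, truth))
  prec <- if (length(found)) tp / length(found) else 0
  rec <- if (length(truth)) tp / length(truth) else 1
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Adjusted Rand index between two labelings (independent of any package).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Run one planted-switch recovery and return the F1 score.
switch_recovery_f1 <- function(seed, n_modules = 2, n_switch = 2,
                               module_size = 20, r = 0.9,
                               threshold = 0.6) {
  cfg <- simulation_config(
    n_genes = 100,
    module_spec = replicate(n_modules, list(size = module_size, r = r),
                            simplify = FALSE),
    n_switch = n_switch, seed = seed)
  net <- plant_network_structure(cfg)
  g <- build_correlation_network(net$experiment, threshold = threshold)
  carto <- suppressMessages(
    node_cartography(g, net$experiment, k_range = 2:8, seed = seed))
  found <- find_switch_genes(carto$topology)$gene_id
  list(f1 = f1_score(found, net$truth$switch_genes),
       topology = carto$topology, found = found,
       truth = net$truth$switch_genes)
}
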