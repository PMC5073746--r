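# Oracles: every statistic is recomputed by an independent brute-force
# route (explicit sums, stats::aov, closed forms) on small fixtures.

random_groups_fixture <- function(n_genes = 20, groups = gl(4, 3),
                                  seed = 99) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * length(groups), 8, 1), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              paste0("s", seq_along(groups))))
  list(x = x, groups = groups)
}

test_that("SAM d matches a brute-force per-gene computation", {
  fx <- random_groups_fixture()
  set.seed(1)
  res <- sam_multiclass(fx$x, fx$groups, n_perm = 100, s0 = 0.2)
  oracle_d <- apply(fx$x, 1, function(v) {
    means <- tapply(v, fx$groups, mean)
    nn <- table(fx$groups)
    r <- sqrt(sum(nn * (means - mean(v))^2))
    within <- sum((v - means[fx$groups])^2)
    s <- sqrt(sum(1 / nn) * within / (length(v) - length(nn)))
    r / (s + 0.2)
  })
  expect_equal(unname(res$d), unname(oracle_d), tolerance = 1e-10)
})

test_that("a constant gene scores d = 0 and is never significant", {
  fx <- random_groups_fixture(n_genes = 10)
  fx$x[1, ] <- 7.3
  set.seed(2)
  res <- sam_multiclass(fx$x, fx$groups, n_perm = 100)
  expect_equal(unname(res$d[1]), 0)
  expect_false(res$significant[[1]])
})

test_that("SAM recovers strong planted one-class shifts with few extras", {
  # at 5x the replicate noise, recovery on this fixture is complete;
  # across fixtures it is 49-50 of 50
  set.seed(2)
  groups <- gl(12, 3)
  x <- matrix(rnorm(1000 * 36, 8, 0.25), 1000,
              dimnames = list(sprintf("g%04d", 1:1000), NULL))
  planted <- sample(1000, 50)
  x[planted, groups == "1"] <- x[planted, groups == "1"] + 5 * 0.25
  res <- sam_multiclass(x, groups, n_perm = 300, fdr_percent = 0.1)
  called <- which(res$significant)
  expect_true(all(planted %in% called))
  expect_lte(length(setdiff(called, planted)), 1)
})

test_that("SAM and ANOVA selections shrink as thresholds tighten", {
  fx <- random_groups_fixture(n_genes = 50, seed = 5)
  fx$x[1:5, fx$groups == 1] <- fx$x[1:5, fx$groups == 1] + 3
  set.seed(3)
  loose <- sam_multiclass(fx$x, fx$groups, n_perm = 100, fdr_percent = 5)
  set.seed(3)
  tight <- sam_multiclass(fx$x, fx$groups, n_perm = 100, fdr_percent = 0.1)
  expect_true(all(which(tight$significant) %in% which(loose$significant)))

  a_loose <- anova_bonferroni(fx$x, fx$groups, alpha = 0.05)
  a_tight <- anova_bonferroni(fx$x, fx$groups, alpha = 0.001)
  expect_true(all(a_tight$gene_id[a_tight$selected] %in%
                    a_loose$gene_id[a_loose$selected]))
})

test_that("ANOVA F and p match stats::aov and a sum-of-squares oracle", {
  fx <- random_groups_fixture(n_genes = 12, seed = 7)
  res <- anova_bonferroni(fx$x, fx$groups, alpha = 0.01)
  for (i in c(1, 5, 12)) {
    fit <- summary(aov(fx$x[i, ] ~ fx$groups))[[1]]
    expect_equal(res$F[i], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # identical groups: F = 0, not selected
  x0 <- matrix(rep(c(1, 2, 3), 2), 1, dimnames = list("flat", NULL))
  r0 <- anova_bonferroni(x0, gl(2, 3), alpha = 0.01)
  expect_equal(r0$F, 0)
  expect_false(r0$selected)
  # Bonferroni: selected iff p * n_genes <= alpha
  expect_equal(res$selected, res$p * 12 <= 0.01)
})

test_that("fold change arithmetic and antisymmetry hold", {
  x <- rbind(a = c(8, 8, 10, 10), b = c(10, 10, 9.2, 9.2),
             c = c(5, 5, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  fc <- fold_change(x, c("s1", "s2"), c("s3", "s4"))
  expect_equal(unname(fc), c(2, -0.8, 0))
  expect_true(abs(fc[["a"]]) >= 1 && abs(fc[["a"]]) >= log2(3))
  expect_false(abs(fc[["b"]]) >= 1)
  rev_fc <- fold_change(x, c("s3", "s4"), c("s1", "s2"))
  expect_equal(unname(fc), -unname(rev_fc))
  expect_error(fold_change(x, character(0), "s1"), "nonempty")
})

test_that("Welch t matches stats::t.test to 1e-10", {
  x <- rbind(g1 = c(8, 8.1, 7.9, 11, 11.2, 10.8),
             g2 = c(8, 8.2, 7.8, 8.1, 7.9, 8.0))
  colnames(x) <- paste0("s", 1:6)
  res <- welch_t(x, paste0("s", 1:3), paste0("s", 4:6))
  for (i in 1:2) {
    or <- t.test(x[i, 4:6], x[i, 1:3], var.equal = FALSE)
    expect_equal(res$t[i], unname(or$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], or$p.value, tolerance = 1e-10)
  }
})

test_that("t + FC selection respects both filters and flags direction", {
  design <- make_design(n_timepoints = 1, n_replicates = 3)
  vals <- rbind(
    strong_up   = c(8, 8.1, 7.9, 11, 11.2, 10.8),  # selected, up
    fc_only     = c(8, 6, 10, 11, 9, 13),           # FC ok, p too big
    p_only      = c(8, 8.01, 7.99, 8.5, 8.51, 8.49),# p ok, FC < 2
    null_gene   = c(8, 8.1, 7.9, 8, 8.1, 7.9))
  colnames(vals) <- design$sample_id
  x <- ws_experiment(vals, design)
  tb <- select_de_timepoint(x, 0, genotype = "MP")
  expect_equal(tb$gene_id[tb$selected], "strong_up")
  expect_equal(tb$direction[tb$selected], "up")
  # monotone flags: joint filter is a subset of the FC filter alone
  expect_true(all(abs(tb$log2fc[tb$selected]) >= 1))
})

test_that("identical WW and WS replicate sets select nothing", {
  design <- make_design(n_timepoints = 1, n_replicates = 3)
  vals <- matrix(rep(c(8, 8.1, 7.9), each = 1, times = 2), 2, 6,
                 byrow = TRUE,
                 dimnames = list(c("a", "b"), design$sample_id))
  vals["a", ] <- c(8, 8.1, 7.9, 8, 8.1, 7.9)
  vals["b", ] <- c(5, 5.2, 4.8, 5, 5.2, 4.8)
  x <- ws_experiment(vals, design)
  tb <- select_de_timepoint(x, 0, genotype = "MP")
  expect_false(any(tb$selected))
})

test_that("the faster genotype selects more genes at the early timepoint", {
  # genotype lag: MP responds at the planted time, SG one step later
  cfg <- simulation_config(n_genes = 400, de_fraction = 0.15,
                           profile_counts = c(up_sustained = 60),
                           genotype_lag = TRUE, seed = 21)
  sim <- simulate_experiment(cfg)
  mp <- ttest_fc_select(sim$experiment, genotype = "MP")
  sg <- ttest_fc_select(sim$experiment, genotype = "SG")
  expect_gt(length(mp$sets$t0), length(sg$sets$t0))
})

test_that("the union ledger obeys inclusion-exclusion", {
  a <- sprintf("g%04d", 1:1188)
  b <- sprintf("g%04d", 889:1325)
  led <- ws_union_ledger(a, b)
  expect_equal(led$n_a, 1188)
  expect_equal(led$n_b, 437)
  expect_equal(led$n_intersect, 300)
  expect_equal(led$n_union, 1325)
  expect_equal(led$n_union, led$n_a + led$n_b - led$n_intersect)
  # disjoint and nested cases
  expect_equal(ws_union_ledger(c("x", "y", "z"), c("u", "v"))$n_union, 5)
  expect_equal(ws_union_ledger(a, a[1:10])$n_union, length(a))
  # annotated subset
  ann <- setNames(c("kinase", "", "HSP"), c("g0001", "g0002", "g0003"))
  led2 <- ws_union_ledger(c("g0001", "g0002"), c("g0003"), ann)
  expect_equal(led2$annotated_union, c("g0001", "g0003"))
})

test_that("direction splits count signs and respect antisymmetry", {
  fc <- setNames(c(rep(1.5, 765), rep(-2, 471)), sprintf("g%04d", 1:1236))
  ds <- direction_split(fc, names(fc))
  expect_equal(ds$n_up, 765)
  expect_equal(ds$n_down, 471)
  expect_equal(ds$total, 1236)
  flipped <- direction_split(-fc, names(fc))
  expect_equal(flipped$n_up, ds$n_down)
  expect_equal(flipped$n_down, ds$n_up)
})

test_that("overlap percentages round as printed", {
  a <- sprintf("L%03d", 1:200)
  b <- c(a[1:48], sprintf("B%03d", 1:221))   # 48 of 269 shared
  ov <- overlap_percent(a, b)
  expect_equal(ov$n_overlap, 48)
  expect_equal(ov$n_total, 269)
  expect_equal(ov$percent, 18)
})

test_that("FC ranking orders descending with id tie-breaks", {
  set.seed(31)
  fc <- setNames(round(rnorm(50), 3), sprintf("g%02d", 1:50))
  fc[c("g07", "g03")] <- 1.5   # tie
  rk <- rank_by_fc(fc, top_n = 50, bottom_n = 0)
  oracle <- names(fc)[order(-fc, names(fc))]
  expect_equal(rk$top$gene_id, oracle)
  tie_pos <- which(rk$top$gene_id %in% c("g03", "g07"))
  expect_equal(rk$top$gene_id[tie_pos], c("g03", "g07"))
  # fewer than requested: return all with a message
  ann <- setNames(rep("x", 5), sprintf("g%02d", 1:5))
  expect_message(small <- rank_by_fc(fc, top_n = 20, annotation = ann,
                                     annotated_only = TRUE), "fewer")
  expect_equal(nrow(small$top), 5)
})

test_that("row-median normalization zeroes every row median", {
  expect_equal(unname(row_median_normalize(matrix(7.3, 1, 5,
    dimnames = list("a", NULL)))[1, ]), rep(0, 5))
  expect_equal(unname(row_median_normalize(matrix(c(1, 2, 3), 1,
    dimnames = list("a", NULL)))[1, ]), c(-1, 0, 1))
  set.seed(41)
  m <- matrix(rnorm(200), 20, dimnames = list(sprintf("g%02d", 1:20), NULL))
  norm <- row_median_normalize(m)
  expect_true(all(abs(apply(norm, 1, median)) < 1e-12))
})

test_that("PCA loading extremes report explained variance and are sign-stable", {
  # rank-1 matrix: one latent factor explains everything
  u <- rnorm(30); v <- rnorm(6)
  m1 <- outer(u, v)
  rownames(m1) <- sprintf("g%02d", 1:30)
  m1 <- m1 - rowMeans(m1) + 8   # keep rank 1 after centering
  res1 <- pca_loading_extremes(m1)
  expect_equal(res1$explained, 1.0, tolerance = 1e-8)
  expect_error(pca_loading_extremes(m1, component = 5), "rank")

  # uniformly spaced loadings: one gene in each 1% tail of 100
  set.seed(51)
  load <- seq(-1, 1, length.out = 100)
  m2 <- outer(load, rnorm(8)) + matrix(rnorm(800, 0, 1e-6), 100)
  rownames(m2) <- sprintf("g%03d", 1:100)
  res2 <- pca_loading_extremes(m2)
  expect_length(res2$low, 1)
  expect_length(res2$high, 1)

  # sign invariance: a decomposition with flipped loadings gives the
  # same gene sets
  res_neg <- pca_loading_extremes(-m2)
  expect_setequal(c(res2$low, res2$high), c(res_neg$low, res_neg$high))
})

test_that("hierarchical ordering matches a brute-force average-linkage oracle", {
  # identical rows sit at distance 0 and adjacent leaves
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 4, 2),
             d = c(4, 3, 2, 1))
  res <- hierarchical_order(m, distance = "pearson")
  pos <- match(c("a", "b"), res$labels)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(min(res$hclust$height), 0)
  # perfectly anti-correlated rows: distance 2
  m2 <- rbind(u = c(1, 2, 3), v = c(3, 2, 1))
  res2 <- hierarchical_order(m2, distance = "pearson")
  expect_equal(res2$hclust$height, 2)

  # 4-row Euclidean fixture against a hand-rolled average-linkage merge
  set.seed(61)
  m3 <- matrix(rnorm(16), 4, dimnames = list(letters[1:4], NULL))
  res3 <- hierarchical_order(m3, distance = "euclidean")
  brute_average_linkage <- function(dmat) {
    clusters <- as.list(seq_len(nrow(dmat)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
      heights <- c(heights, best[1])
      clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters[[best[3]]] <- NULL
    }
    heights
  }
  oracle_heights <- brute_average_linkage(as.matrix(dist(m3)))
  expect_equal(res3$hclust$height, oracle_heights, tolerance = 1e-10)
})
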