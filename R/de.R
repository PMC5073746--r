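# Staged gene-selection statistics: multiclass SAM, one-way ANOVA with
# Bonferroni correction, per-contrast fold change and Welch t selection,
# set accounting, FC ranking, row-median normalization and PCA loading
# extraction.

# ---- internal vectorized score engines ------------------------------------

# Per-gene one-way sums of squares for a genes x samples matrix.
# Returns between-class SS, pooled within variance and class sizes.
oneway_ss <- function(x, f) {
  f <- droplevels(as.factor(f))
  nn <- as.vector(table(f))
  K <- nlevels(f)
  n <- ncol(x)
  ind <- stats::model.matrix(~ f - 1)           # n x K indicator
  gm <- (x %*% ind) %*% diag(1 / nn, K)          # genes x K class means
  grand <- rowMeans(x)
  between <- drop((gm - grand)^2 %*% nn)         # sum_k n_k (m_k - m)^2
  within <- rowSums(x^2) - drop(gm^2 %*% nn)     # total SS - class-mean SS
  within <- pmax(within, 0)
  list(between = between, within = within, nn = nn, K = K, n = n, gm = gm)
}

# SAM multiclass signal and spread: r = sqrt(between-class SS),
# s = sqrt((sum 1/n_k) * pooled within variance).
sam_rs <- function(x, f) {
  ss <- oneway_ss(x, f)
  r <- sqrt(ss$between)
  s <- sqrt(sum(1 / ss$nn) * ss$within / (ss$n - ss$K))
  list(r = r, s = s)
}

# Tusher-style fudge factor: the percentile of {s_i} minimizing the
# coefficient of variation of mad(d) across windows of s.
choose_s0 <- function(r, s) {
  if (all(s == 0)) return(0)
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                 names = FALSE))
  brk <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.01),
                                names = FALSE))
  if (length(brk) < 3) return(stats::median(s))
  win <- cut(s, breaks = brk, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(NA_real_)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  if (all(is.na(cv))) return(stats::median(s))
  cand[which.min(cv)]
}

# ---- SAM ------------------------------------------------------------------

#' Multiclass significance analysis of microarrays (SAM)
#'
#' Permutation-calibrated multiclass screen. The per-gene statistic is
#' `d_i = r_i / (s_i + s0)` with `r_i` the square root of the between-class
#' sum of squares, `s_i` the pooled standard error
#' `sqrt((sum_k 1/n_k) * SS_within / (n - K))`, and `s0` a fudge factor
#' chosen as the percentile of the `s_i` minimizing the coefficient of
#' variation of `d` across windows of `s` (or supplied directly). Because
#' the multiclass `d` is non-negative, significance is one-sided: the cut
#' on `d` is the lowest observed value whose median permutation false-call
#' estimate keeps the FDR at or below `fdr_percent`.
#'
#' Group labels are permuted across samples; uses the current RNG state, so
#' set a seed for reproducibility.
#'
#' @param x genes x samples matrix (log2 scale) or a [ws_experiment].
#' @param groups class label per sample (coerced to factor), `K >= 2`
#'   classes with at least 2 samples each.
#' @param n_perm number of label permutations (`>= 100`).
#' @param fdr_percent target median FDR, in percent (default 0.1).
#' @param s0 optional numeric fudge factor; `NULL` selects it automatically.
#' @return list of class `sam_result`: `d` (named per-gene statistic),
#'   `s0`, `cut` (d threshold; `Inf` when nothing is called),
#'   `significant` (named logical), `n_called`, `fdr_table` (candidate
#'   cuts with called counts and estimated FDR), `n_perm`.
#' @export
sam_multiclass <- function(x, groups, n_perm = 300, fdr_percent = 0.1,
                           s0 = NULL) {
  x <- expr_values(x)
  f <- droplevels(as.factor(groups))
  if (length(f) != ncol(x))
    stop("`groups` must have one label per sample column")
  if (nlevels(f) < 2) stop("need at least 2 classes")
  if (any(table(f) < 2))
    stop("class with fewer than 2 samples: ",
         paste(names(which(table(f) < 2)), collapse = ", "))
  if (n_perm < 100) stop("n_perm must be at least 100")
  G <- nrow(x)

  sc <- sam_rs(x, f)
  if (is.null(s0)) s0 <- choose_s0(sc$r, sc$s)
  d <- sc$r / (sc$s + s0)
  d[sc$r == 0] <- 0            # constant genes: no signal by definition
  d[!is.finite(d)] <- 0
  names(d) <- rownames(x)

  perm_sorted <- matrix(0, G, n_perm)
  for (b in seq_len(n_perm)) {
    pf <- sample(f)
    ps <- sam_rs(x, pf)
    pd <- ps$r / (ps$s + s0)
    pd[ps$r == 0] <- 0
    pd[!is.finite(pd)] <- 0
    perm_sorted[, b] <- sort(pd)
  }

  cuts <- sort(unique(d[d > 0]), decreasing = TRUE)
  if (length(cuts)) {
    false_med <- numeric(length(cuts))
    counts <- matrix(0, length(cuts), n_perm)
    for (b in seq_len(n_perm))
      counts[, b] <- G - findInterval(cuts - 1e-12, perm_sorted[, b])
    false_med <- apply(counts, 1L, stats::median)
    called <- vapply(cuts, function(ct) sum(d >= ct), numeric(1))
    fdr <- false_med / pmax(called, 1)
    fdr_table <- data.frame(cut = cuts, n_called = called,
                            median_false = false_med, fdr_percent = 100 * fdr)
    ok <- which(fdr <= fdr_percent / 100)
  } else {
    fdr_table <- data.frame(cut = numeric(0), n_called = numeric(0),
                            median_false = numeric(0),
                            fdr_percent = numeric(0))
    ok <- integer(0)
  }
  if (length(ok)) {
    best <- ok[which.max(fdr_table$n_called[ok])]
    cut <- fdr_table$cut[best]
  } else {
    cut <- Inf
  }
  significant <- d >= cut
  structure(list(d = d, s0 = s0, cut = cut, significant = significant,
                 n_called = sum(significant), fdr_table = fdr_table,
                 n_perm = n_perm),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("sam_result: ", length(x$d), " genes, s0 = ", signif(x$s0, 4),
      ", called ", x$n_called, " at cut ", signif(x$cut, 4), "\n", sep = "")
  invisible(x)
}

# ---- ANOVA ----------------------------------------------------------------

#' One-way ANOVA per gene with standard Bonferroni selection
#'
#' A gene is selected iff `p * n_genes_tested <= alpha`. Genes with zero
#' variance everywhere (F undefined) are never selected; their count is
#' reported with a message. Zero within-group variance with unequal means
#' gives `p = 0` (selected).
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param groups class label per sample; `K >= 2`, each class `>= 2`.
#' @param alpha family-wise threshold (default 0.01).
#' @return data.frame with `gene_id`, `F`, `p`, `p_bonf`, `selected`.
#' @export
anova_bonferroni <- function(x, groups, alpha = 0.01) {
  x <- expr_values(x)
  f <- droplevels(as.factor(groups))
  if (length(f) != ncol(x))
    stop("`groups` must have one label per sample column")
  if (nlevels(f) < 2) stop("need at least 2 classes")
  if (any(table(f) < 2))
    stop("class with fewer than 2 samples: ",
         paste(names(which(table(f) < 2)), collapse = ", "))
  ss <- oneway_ss(x, f)
  Fstat <- (ss$between / (ss$K - 1)) / (ss$within / (ss$n - ss$K))
  # 0/0: constant gene -> undefined, not selected
  undef <- ss$within == 0 & ss$between == 0
  Fstat[undef] <- NA_real_
  p <- stats::pf(Fstat, ss$K - 1, ss$n - ss$K, lower.tail = FALSE)
  G <- nrow(x)
  p_bonf <- pmin(p * G, 1)
  selected <- !is.na(p) & p * G <= alpha
  if (any(undef))
    message(sum(undef), " gene(s) with undefined F (constant), not selected")
  data.frame(gene_id = rownames(x), F = Fstat, p = p, p_bonf = p_bonf,
             selected = selected, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- fold change and Welch t ----------------------------------------------

#' Per-gene log2 fold change between two sample groups
#'
#' `log2fc = mean(log2 B) - mean(log2 A)` on the log2-scale matrix. A fold
#' change filter `FC >= f` corresponds to `|log2fc| >= log2(f)`.
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param samples_a,samples_b column names (or indices) of the reference
#'   (A) and test (B) groups; both nonempty.
#' @return named numeric vector of log2 fold changes.
#' @export
fold_change <- function(x, samples_a, samples_b) {
  x <- expr_values(x)
  if (!length(samples_a) || !length(samples_b))
    stop("both contrast groups must be nonempty")
  rowMeans(x[, samples_b, drop = FALSE]) -
    rowMeans(x[, samples_a, drop = FALSE])
}

#' Per-gene Welch (unequal-variance) t-test between two groups
#'
#' Vectorized over genes. When both groups have zero variance: equal means
#' give `p = NA` (excluded downstream, counted via message), unequal means
#' give `p = 0`.
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param samples_a,samples_b column names of the two groups (`>= 2` each).
#' @return data.frame with `gene_id`, `t`, `df`, `p`.
#' @export
welch_t <- function(x, samples_a, samples_b) {
  x <- expr_values(x)
  a <- x[, samples_a, drop = FALSE]
  b <- x[, samples_b, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 replicates")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(m1[zero] == m2[zero], NA_real_, 0)
    message(sum(zero & m1 == m2),
            " gene(s) with zero variance and equal means, excluded")
  }
  data.frame(gene_id = rownames(x), t = tstat, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch t + fold-change selection at one timepoint
#'
#' Selects genes with Welch `p < p_thresh` and `|log2fc| >= log2(fc_thresh)`
#' (strict `>` when `fc_strict = TRUE`, e.g. the `FC > 1.7` rule) for the
#' WW vs WS contrast at one timepoint, optionally within one genotype.
#'
#' @param x a [ws_experiment].
#' @param timepoint ordinal timepoint index.
#' @param genotype optional genotype; `NULL` pools genotypes.
#' @param p_thresh t-test threshold (default 0.01).
#' @param fc_thresh fold-change threshold on the linear scale (default 2).
#' @param fc_strict use strict inequality for the FC filter.
#' @param genes optional gene subset to test.
#' @return data.frame with `gene_id`, `log2fc`, `t`, `p`, `selected`,
#'   `direction` (`"up"`/`"down"`/`NA`).
#' @export
select_de_timepoint <- function(x, timepoint, genotype = NULL,
                                p_thresh = 0.01, fc_thresh = 2,
                                fc_strict = FALSE, genes = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  ww <- samples_for(x, genotype = genotype, treatment = "WW",
                    timepoint = timepoint)
  ws <- samples_for(x, genotype = genotype, treatment = "WS",
                    timepoint = timepoint)
  if (!length(ww) || !length(ws))
    stop("missing WW or WS cell at timepoint ", timepoint,
         if (!is.null(genotype)) paste0(" for genotype ", genotype))
  m <- x$values
  if (!is.null(genes)) m <- m[intersect(rownames(m), genes), , drop = FALSE]
  fc <- fold_change(m, ww, ws)
  tt <- welch_t(m, ww, ws)
  lfc_cut <- log2(fc_thresh)
  fc_pass <- if (fc_strict) abs(fc) > lfc_cut else abs(fc) >= lfc_cut
  selected <- !is.na(tt$p) & tt$p < p_thresh & fc_pass
  data.frame(gene_id = tt$gene_id, log2fc = unname(fc), t = tt$t, p = tt$p,
             selected = selected,
             direction = ifelse(selected, ifelse(fc > 0, "up", "down"), NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-genotype, per-timepoint t-test + fold-change selection
#'
#' Applies [select_de_timepoint()] at every timepoint for one genotype and
#' reports the selected sets with up/down counts.
#'
#' @inheritParams select_de_timepoint
#' @return list with `tables` (per-timepoint data.frames), `sets`
#'   (per-timepoint selected gene ids), `counts` (data.frame timepoint,
#'   n_up, n_down, n_selected), and `genes` (union over timepoints).
#' @export
ttest_fc_select <- function(x, genotype = NULL, p_thresh = 0.01,
                            fc_thresh = 2, fc_strict = FALSE, genes = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  tps <- sort(unique(x$design$timepoint[x$design$treatment %in%
                                          c("WW", "WS")]))
  tables <- lapply(tps, function(tp)
    select_de_timepoint(x, tp, genotype = genotype, p_thresh = p_thresh,
                        fc_thresh = fc_thresh, fc_strict = fc_strict,
                        genes = genes))
  names(tables) <- paste0("t", tps)
  sets <- lapply(tables, function(tb) tb$gene_id[tb$selected])
  counts <- data.frame(
    timepoint = tps,
    n_up = vapply(tables, function(tb) sum(tb$direction == "up",
                                           na.rm = TRUE), numeric(1)),
    n_down = vapply(tables, function(tb) sum(tb$direction == "down",
                                             na.rm = TRUE), numeric(1)),
    row.names = NULL)
  counts$n_selected <- counts$n_up + counts$n_down
  list(tables = tables, sets = sets, counts = counts,
       genes = sort(unique(unlist(sets))))
}

# ---- set accounting -------------------------------------------------------

#' Venn ledger for genotype-specific vs treatment-only selections
#'
#' Inclusion-exclusion accounting of two selection routes over the same
#' gene universe, plus the functionally annotated subset of the union.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param annotation optional named character vector mapping gene id to an
#'   annotation string; empty string or missing id means unannotated.
#' @return list with `n_a`, `n_b`, `n_intersect`, `n_union`, `union`,
#'   `intersect`, `annotated_union` and `n_annotated`.
#' @export
ws_union_ledger <- function(set_a, set_b, annotation = NULL) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  un <- union(set_a, set_b)
  iv <- intersect(set_a, set_b)
  annotated <- if (is.null(annotation)) character(0) else {
    ann <- annotation[un]
    un[!is.na(ann) & nzchar(ann)]
  }
  list(n_a = length(set_a), n_b = length(set_b),
       n_intersect = length(iv), n_union = length(un),
       union = sort(un), intersect = sort(iv),
       annotated_union = sort(annotated), n_annotated = length(annotated))
}

#' Up/down split of a selected contrast
#'
#' @param log2fc named per-gene log2 fold changes.
#' @param selected gene ids (or logical over `log2fc`) of the selected set.
#' @return list `n_up`, `n_down`, `total`.
#' @export
direction_split <- function(log2fc, selected) {
  fc <- if (is.logical(selected)) log2fc[selected] else log2fc[selected]
  list(n_up = sum(fc > 0), n_down = sum(fc < 0),
       total = sum(fc > 0) + sum(fc < 0))
}

#' Percentage of one gene set found in another
#'
#' Rounded percentage of `set_b` members also present in `set_a`,
#' e.g. shared berry/leaf stress-modulated genes.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param digits rounding digits (default 0).
#' @return list `n_overlap`, `n_total`, `percent`.
#' @export
overlap_percent <- function(set_a, set_b, digits = 0) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  list(n_overlap = k, n_total = length(set_b),
       percent = round(100 * k / length(set_b), digits))
}

#' Rank genes by log2 fold change, top and bottom slices
#'
#' Descending order, ties broken by gene id ascending. With
#' `annotated_only`, unannotated genes are dropped before ranking. When
#' fewer genes than requested are available all are returned (message).
#'
#' @param log2fc named per-gene log2 fold changes.
#' @param top_n,bottom_n slice sizes (default 20 each).
#' @param annotation named annotation vector (needed for
#'   `annotated_only`).
#' @param annotated_only drop unannotated genes first.
#' @return list `top` and `bottom`: data.frames `gene_id`, `log2fc` in
#'   rank order (bottom ordered most-negative first).
#' @export
rank_by_fc <- function(log2fc, top_n = 20, bottom_n = 20,
                       annotation = NULL, annotated_only = FALSE) {
  ids <- names(log2fc)
  if (annotated_only) {
    if (is.null(annotation)) stop("annotated_only requires `annotation`")
    ann <- annotation[ids]
    keep <- !is.na(ann) & nzchar(ann)
    log2fc <- log2fc[keep]; ids <- ids[keep]
  }
  ord <- order(-log2fc, ids)
  ranked <- data.frame(gene_id = ids[ord], log2fc = unname(log2fc[ord]),
                       stringsAsFactors = FALSE)
  if (nrow(ranked) < top_n || nrow(ranked) < bottom_n)
    message("fewer genes (", nrow(ranked), ") than requested; returning all")
  top <- utils::head(ranked, min(top_n, nrow(ranked)))
  bottom <- utils::tail(ranked, min(bottom_n, nrow(ranked)))
  bottom <- bottom[rev(seq_len(nrow(bottom))), ]
  rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}

# ---- matrix utilities ------------------------------------------------------

#' Row-median normalization
#'
#' Subtracts each row's median (log2 scale), so output row medians are 0.
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @return matrix of the same shape.
#' @export
row_median_normalize <- function(x) {
  m <- expr_values(x)
  sweep(m, 1L, apply(m, 1L, stats::median))
}

#' Extreme PCA loadings on one component
#'
#' Rows (genes) are centered, the matrix decomposed by SVD, and the genes
#' whose loading on the chosen component falls strictly below the
#' `percentile`-th or strictly above the `(100 - percentile)`-th percentile
#' are returned, together with the component's explained-variance
#' fraction. The loading sign is canonicalized (largest-magnitude loading
#' positive), so results are invariant to the sign ambiguity of the
#' decomposition.
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param component principal component index (default 1).
#' @param percentile tail size in percent (default 1).
#' @return list `low`, `high` (gene id vectors), `explained` (fraction),
#'   `loadings` (named vector).
#' @export
pca_loading_extremes <- function(x, component = 1, percentile = 1) {
  m <- expr_values(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  mc <- m - rowMeans(m)
  sv <- svd(mc)
  tol <- max(dim(mc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (component > rank)
    stop("component ", component, " exceeds matrix rank ", rank)
  load <- sv$u[, component] * sv$d[component]
  if (load[which.max(abs(load))] < 0) load <- -load
  names(load) <- rownames(m)
  explained <- sv$d[component]^2 / sum(sv$d^2)
  lo <- stats::quantile(load, percentile / 100, names = FALSE)
  hi <- stats::quantile(load, 1 - percentile / 100, names = FALSE)
  list(low = names(load)[load < lo], high = names(load)[load > hi],
       explained = explained, loadings = load)
}

#' Average-linkage hierarchical leaf order
#'
#' Agglomerative clustering of rows with Pearson correlation distance
#' (`1 - r`) or Euclidean distance, for heat-map row ordering. Under the
#' Pearson metric, distances involving a zero-variance row are defined as
#' 1 (message reports how many).
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param distance `"pearson"` or `"euclidean"`.
#' @return list `order` (row indices), `labels` (gene ids in leaf order),
#'   `hclust` (the fitted tree).
#' @export
hierarchical_order <- function(x, distance = c("pearson", "euclidean")) {
  m <- expr_values(x)
  distance <- match.arg(distance)
  if (nrow(m) < 2) stop("need at least 2 rows")
  if (distance == "pearson") {
    cc <- suppressWarnings(stats::cor(t(m)))
    nbad <- sum(!stats::complete.cases(cc))
    if (nbad) message(nbad, " zero-variance row(s): Pearson distance set to 1")
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = "average")
  list(order = hc$order, labels = rownames(m)[hc$order], hclust = hc)
}

# ---- full cascade ----------------------------------------------------------

#' Full staged differential-expression cascade
#'
#' Runs the two selection routes and merges them: (A) a 12-class screen
#' (genotype x treatment x timepoint) by multiclass SAM, skimmed by one-way
#' ANOVA with Bonferroni correction, then per-genotype, per-timepoint Welch
#' t + fold-change selection restricted to the surviving genes; (B) the
#' same screen over 6 treatment x timepoint classes pooling genotypes,
#' followed by pooled per-timepoint t + FC selection. The ledger reports
#' the union by inclusion-exclusion.
#'
#' @param x a [ws_experiment] with WW and WS samples.
#' @param cfg a [pipeline_config()] list (thresholds and permutation count).
#' @param annotation optional named annotation vector for the ledger.
#' @return list with `sam12`, `anova12`, `sam6`, `anova6`, `per_genotype`
#'   (route-A selections), `pooled` (route-B selections), `set_a`, `set_b`,
#'   `ledger`.
#' @export
run_de_cascade <- function(x, cfg = pipeline_config(), annotation = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  keep <- x$design$treatment %in% c("WW", "WS")
  d <- x$design[keep, ]
  m <- x$values[, d$sample_id, drop = FALSE]
  g12 <- interaction(d$genotype, d$treatment, d$timepoint, drop = TRUE)
  g6 <- interaction(d$treatment, d$timepoint, drop = TRUE)
  sub <- ws_experiment(m, d, timepoint_labels = x$timepoint_labels)

  sam12 <- sam_multiclass(m, g12, n_perm = cfg$sam_n_perm,
                          fdr_percent = cfg$sam_fdr_percent)
  surv12 <- names(sam12$significant)[sam12$significant]
  anova12 <- if (length(surv12)) {
    a <- anova_bonferroni(m[surv12, , drop = FALSE], g12,
                          alpha = cfg$anova_alpha)
    a$gene_id[a$selected]
  } else character(0)

  genotypes <- sort(unique(d$genotype))
  per_genotype <- lapply(genotypes, function(gt)
    ttest_fc_select(sub, genotype = gt, p_thresh = cfg$ttest_p,
                    fc_thresh = cfg$fc_threshold, genes = anova12))
  names(per_genotype) <- genotypes
  set_a <- sort(unique(unlist(lapply(per_genotype, `[[`, "genes"))))

  sam6 <- sam_multiclass(m, g6, n_perm = cfg$sam_n_perm,
                         fdr_percent = cfg$sam_fdr_percent)
  surv6 <- names(sam6$significant)[sam6$significant]
  anova6 <- if (length(surv6)) {
    a <- anova_bonferroni(m[surv6, , drop = FALSE], g6,
                          alpha = cfg$anova_alpha)
    a$gene_id[a$selected]
  } else character(0)
  pooled <- ttest_fc_select(sub, genotype = NULL, p_thresh = cfg$ttest_p,
                            fc_thresh = cfg$fc_threshold, genes = anova6)
  set_b <- pooled$genes

  list(sam12 = sam12, anova12 = anova12, sam6 = sam6, anova6 = anova6,
       per_genotype = per_genotype, pooled = pooled,
       set_a = set_a, set_b = set_b,
       ledger = ws_union_ledger(set_a, set_b, annotation))
}
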