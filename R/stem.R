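# Short time-series model-profile clustering: candidate enumeration,
# greedy max-min profile selection, correlation assignment, permutation
# significance, and the two-genotype profile comparison.

# Correlation between rows of two matrices of level/series vectors, with
# the convention that a zero-variance vector has correlation NA.
safe_cor <- function(a, b) {
  suppressWarnings(stats::cor(t(a), t(b)))
}

#' Zero-anchored WS-vs-WW fold-change series
#'
#' For each gene and one genotype, the vector
#' `[0, log2fc(t0), log2fc(t1), ..., log2fc(T-1)]` of WS - WW mean log2
#' differences, anchored at 0 before the first observation.
#'
#' @param x a [ws_experiment].
#' @param genotype genotype to extract (or `NULL` to pool genotypes).
#' @param genes optional gene subset.
#' @return matrix genes x (T+1), first column zero.
#' @export
build_fc_series <- function(x, genotype = NULL, genes = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  tps <- sort(unique(x$design$timepoint[x$design$treatment %in%
                                          c("WW", "WS")]))
  m <- x$values
  if (!is.null(genes)) m <- m[intersect(rownames(m), genes), , drop = FALSE]
  cols <- lapply(tps, function(tp) {
    ww <- samples_for(x, genotype = genotype, treatment = "WW",
                      timepoint = tp)
    ws <- samples_for(x, genotype = genotype, treatment = "WS",
                      timepoint = tp)
    if (!length(ww) || !length(ws))
      stop("missing ", if (!length(ww)) "WW" else "WS",
           " cell at timepoint ", tp,
           if (!is.null(genotype)) paste0(" for genotype ", genotype))
    fold_change(m, ww, ws)
  })
  series <- cbind(0, do.call(cbind, cols))
  dimnames(series) <- list(rownames(m), c("anchor", paste0("t", tps)))
  series
}

#' Enumerate candidate model profiles
#'
#' All integer step sequences of length `T` starting from level 0 with
#' each step in `[-c, c]`: `(2c+1)^T` candidates, as level vectors of
#' length `T + 1`. Ids follow enumeration order.
#'
#' @param T number of observed timepoints (`>= 1`).
#' @param c maximum unit change per step (`>= 1`).
#' @param drop_flat drop the all-zero profile.
#' @return integer matrix (candidates x (T+1)) with rownames `p<id>`; the
#'   id is kept in attribute `profile_id` column handling via rownames.
#' @export
enumerate_candidate_profiles <- function(T, c = 2, drop_flat = FALSE) {
  stopifnot(T >= 1, c >= 1)
  steps <- expand.grid(rep(list(seq(-c, c)), T))
  levels <- cbind(0L, t(apply(as.matrix(steps), 1L, cumsum)))
  rownames(levels) <- paste0("p", seq_len(nrow(levels)))
  colnames(levels) <- c("anchor", paste0("t", seq_len(T) - 1))
  if (drop_flat) {
    flat <- rowSums(abs(levels)) == 0
    levels <- levels[!flat, , drop = FALSE]
  }
  levels
}

#' Greedy max-min selection of model profiles
#'
#' Distance between candidates is `1 - Pearson r` of their level vectors
#' (distance to a zero-variance/flat vector is 1, and 0 between identical
#' vectors). The selection seeds with the pair at maximum distance and
#' repeatedly adds the candidate maximizing its minimum distance to the
#' chosen set; all ties break to the lowest candidate id (row order).
#'
#' @param candidates matrix from [enumerate_candidate_profiles()].
#' @param m number of profiles to keep (`1 <= m <=` candidate count).
#' @return the selected rows of `candidates`, in candidate-id order.
#' @export
select_model_profiles <- function(candidates, m) {
  n <- nrow(candidates)
  if (m <= 0) stop("m must be positive")
  if (m > n) stop("m exceeds number of candidates")
  if (m == n) return(candidates)
  cc <- safe_cor(candidates, candidates)
  dist <- 1 - cc
  dist[!is.finite(dist)] <- 1          # flat profile: distance 1
  same <- outer(seq_len(n), seq_len(n), function(i, j)
    vapply(seq_along(i), function(k)
      all(candidates[i[k], ] == candidates[j[k], ]), logical(1)))
  dist[same] <- 0
  # seed: pair at maximum distance, lowest ids on ties
  best <- which(dist == max(dist), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  chosen <- as.integer(best[1, ])
  while (length(chosen) < m) {
    rest <- setdiff(seq_len(n), chosen)
    mind <- apply(dist[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[which.max(mind)])  # which.max: lowest id tie
  }
  candidates[sort(chosen), , drop = FALSE]
}

#' Assign gene series to their best-correlated model profile
#'
#' Each gene goes to the profile maximizing the Pearson correlation
#' between its zero-anchored series and the profile's level vector; ties
#' break to the lowest profile id (row order). A zero-variance (flat)
#' series is assigned to the flat profile when present, otherwise left
#' unassigned (`NA`, with a message).
#'
#' @param series genes x (T+1) matrix from [build_fc_series()].
#' @param profiles profiles x (T+1) level matrix.
#' @return list of class `profile_assignment`: `profile` (named character,
#'   profile id per gene, `NA` if unassigned), `counts` (genes per
#'   profile), `n_assigned`, `profiles`.
#' @export
assign_genes <- function(series, profiles) {
  if (!nrow(profiles)) stop("profiles must be nonempty")
  cc <- safe_cor(series, profiles)      # genes x profiles
  flat_profile <- which(rowSums(abs(profiles)) == 0)
  cc[!is.finite(cc)] <- -Inf
  pick <- max.col(cc, ties.method = "first")
  assigned <- rownames(profiles)[pick]
  flat_series <- apply(series, 1L, function(s) stats::var(s) == 0)
  if (any(flat_series)) {
    if (length(flat_profile)) {
      assigned[flat_series] <- rownames(profiles)[flat_profile[1]]
    } else {
      message(sum(flat_series), " flat series left unassigned")
      assigned[flat_series] <- NA_character_
    }
  }
  names(assigned) <- rownames(series)
  counts <- table(factor(assigned, levels = rownames(profiles)))
  structure(list(profile = assigned,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 n_assigned = sum(!is.na(assigned)),
                 profiles = profiles),
            class = "profile_assignment")
}

#' @export
print.profile_assignment <- function(x, ...) {
  cat("profile_assignment: ", x$n_assigned, " genes over ",
      nrow(x$profiles), " profiles\n", sep = "")
  invisible(x)
}

#' Permutation significance of profile gene counts
#'
#' Null counts are obtained by permuting each gene's observed timepoints
#' (the zero anchor stays fixed) and reassigning: exhaustive over all `T!`
#' orderings when `T! <= 5040`, otherwise `n_perm` sampled orderings. The
#' expected count `E_p` is the mean over permutations; the per-profile
#' p-value is the binomial upper tail `P(X >= observed)` with
#' `X ~ Bin(n_assigned, E_p / n_assigned)`; a profile is significant iff
#' `p * m < alpha` (Bonferroni over the `m` profiles).
#'
#' @param assignment a [assign_genes()] result.
#' @param series the series matrix used for the assignment.
#' @param n_perm sampled permutations when exhaustive is infeasible.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `profile`, `observed`, `expected`, `p`,
#'   `p_bonferroni`, `significant`; attribute `n_perm_used`.
#' @export
profile_significance <- function(assignment, series, n_perm = 1000,
                                 alpha = 0.05) {
  stopifnot(inherits(assignment, "profile_assignment"))
  profiles <- assignment$profiles
  m <- nrow(profiles)
  T <- ncol(series) - 1L
  perms <- all_permutations(T)
  if (nrow(perms) > 5040) {
    perms <- t(vapply(seq_len(n_perm), function(i) sample(T),
                      integer(T)))
  }
  B <- nrow(perms)
  null_counts <- matrix(0, B, m, dimnames = list(NULL, rownames(profiles)))
  for (b in seq_len(B)) {
    ps <- series[, c(1L, 1L + perms[b, ]), drop = FALSE]
    a <- suppressMessages(assign_genes(ps, profiles))
    null_counts[b, ] <- a$counts
  }
  expected <- colMeans(null_counts)
  n <- assignment$n_assigned
  obs <- assignment$counts
  p <- vapply(seq_len(m), function(j) {
    pr <- min(1, expected[j] / n)
    stats::pbinom(obs[j] - 1L, n, pr, lower.tail = FALSE)
  }, numeric(1))
  res <- data.frame(profile = rownames(profiles), observed = as.integer(obs),
                    expected = unname(expected), p = p,
                    p_bonferroni = pmin(1, p * m),
                    significant = p * m < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_perm_used") <- B
  res
}

# All permutations of 1..n as a matrix (n! rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Cross-genotype comparison of significant profiles
#'
#' For each significant profile of genotype A, finds the best-correlated
#' partner among genotype B's significant profiles (Pearson r of level
#' vectors), counts the genes assigned to both, and scores the overlap by
#' the hypergeometric upper tail given the two set sizes and the gene
#' universe.
#'
#' @param assign_a,assign_b [assign_genes()] results for the two genotypes
#'   (over the same gene universe).
#' @param sig_a,sig_b [profile_significance()] tables for the two
#'   genotypes.
#' @param universe gene ids of the shared universe.
#' @return data.frame: `profile_a`, `profile_b`, `r`, `n_a`, `n_b`,
#'   `n_intersect`, `p`. Empty (with a message) when B has no significant
#'   profile.
#' @export
compare_genotype_profiles <- function(assign_a, assign_b, sig_a, sig_b,
                                      universe) {
  pa <- sig_a$profile[sig_a$significant]
  pb <- sig_b$profile[sig_b$significant]
  empty <- data.frame(profile_a = character(0), profile_b = character(0),
                      r = numeric(0), n_a = integer(0), n_b = integer(0),
                      n_intersect = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(pa)) return(empty)
  if (!length(pb)) {
    message("no significant profiles in the partner genotype")
    return(empty)
  }
  la <- assign_a$profiles[pa, , drop = FALSE]
  lb <- assign_b$profiles[pb, , drop = FALSE]
  cc <- safe_cor(la, lb)
  cc[!is.finite(cc)] <- -Inf
  N <- length(unique(universe))
  rows <- lapply(seq_along(pa), function(i) {
    j <- which.max(cc[i, ])
    genes_a <- names(assign_a$profile)[!is.na(assign_a$profile) &
                                         assign_a$profile == pa[i]]
    genes_b <- names(assign_b$profile)[!is.na(assign_b$profile) &
                                         assign_b$profile == pb[j]]
    k <- length(intersect(genes_a, genes_b))
    p <- stats::phyper(k - 1, length(genes_a), N - length(genes_a),
                       length(genes_b), lower.tail = FALSE)
    data.frame(profile_a = pa[i], profile_b = pb[j], r = cc[i, j],
               n_a = length(genes_a), n_b = length(genes_b),
               n_intersect = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
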