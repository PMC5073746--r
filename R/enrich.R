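# Hypergeometric overrepresentation of GO-slim terms in gene sets.

#' Hypergeometric term overrepresentation
#'
#' For each term with `K` members in the population of size `N`, and a
#' study set of size `n` hitting the term `k` times, the p-value is the
#' hypergeometric upper tail
#' `p = sum_{x = k}^{min(n, K)} C(K, x) C(N - K, n - x) / C(N, n)`.
#' Terms are intersected with the population first; empty terms are
#' skipped. Results are sorted by ascending p (ties by term id).
#'
#' @param study gene set under test (must be a subset of `population`,
#'   nonempty).
#' @param population background gene set (e.g. all genes on the array).
#' @param term_map named list: term id -> gene ids.
#' @param alpha significance threshold on the corrected p (default 0.01,
#'   the leaf preset; berries use 0.05).
#' @param correction `"none"` (default), `"bonferroni"` or `"bh"`.
#' @return data.frame of class `enrichment_result`: `term`, `k`, `n`,
#'   `K`, `N`, `p`, `p_adj`, `significant`.
#' @export
hypergeometric_enrichment <- function(study, population, term_map,
                                      alpha = 0.01,
                                      correction = c("none", "bonferroni",
                                                     "bh")) {
  correction <- match.arg(correction)
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!length(study)) stop("empty study set")
  extra <- setdiff(study, population)
  if (length(extra))
    stop("study set must be a subset of the population; stray ids: ",
         paste(utils::head(extra, 3), collapse = ", "))
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(term_map), function(tid) {
    members <- intersect(term_map[[tid]], population)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tid, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  out$p_adj <- switch(correction,
                      none = out$p,
                      bonferroni = stats::p.adjust(out$p, "bonferroni"),
                      bh = stats::p.adjust(out$p, "BH"))
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Collapse a term map onto GO-slim ancestors
#'
#' Each term is replaced by its slim ancestors under the (acyclic)
#' `ancestry` relation, a term counting as its own ancestor when it is
#' itself in the slim. Gene sets of terms sharing a slim ancestor are
#' merged (each gene counted once); terms reaching no slim ancestor are
#' dropped.
#'
#' @param term_map named list: term id -> gene ids.
#' @param slim_terms character vector of slim term ids.
#' @param ancestry data.frame with columns `child`, `parent` giving the
#'   direct is-a edges; must be acyclic.
#' @return named list: slim term id -> gene ids.
#' @export
map_to_slim <- function(term_map, slim_terms, ancestry) {
  parents <- split(as.character(ancestry$parent),
                   as.character(ancestry$child))
  memo <- new.env(parent = emptyenv())
  slim_anc <- function(term, path = character(0)) {
    if (term %in% path) stop("cycle detected in ancestry at term ", term)
    if (!is.null(memo[[term]])) return(memo[[term]])
    hits <- if (term %in% slim_terms) term else character(0)
    for (p in parents[[term]])
      hits <- union(hits, slim_anc(p, c(path, term)))
    memo[[term]] <- hits
    hits
  }
  out <- list()
  for (tid in names(term_map)) {
    for (s in slim_anc(tid))
      out[[s]] <- union(out[[s]], term_map[[tid]])
  }
  lapply(out[order(names(out))], sort)
}
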