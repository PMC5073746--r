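# Pearson co-expression network and heat cartography: modules,
# within-module degree z-score (Z), participation coefficient (P), average
# Pearson correlation with neighbours (APCC), seven node-role regions,
# date/party/fight-club hubs and switch genes.

#' Build a thresholded Pearson co-expression network
#'
#' Nodes are genes; an edge joins genes i and j iff `|pearson(i, j)| >=
#' threshold` over the selected samples, with the signed correlation as
#' edge weight. Zero-variance genes are excluded with a message; isolated
#' nodes are retained.
#'
#' @param x genes x samples matrix or [ws_experiment].
#' @param genes optional gene subset (default: all rows).
#' @param samples optional sample subset (default: all columns); at least
#'   3 samples.
#' @param threshold absolute-correlation edge cutoff in (0, 1),
#'   default 0.6.
#' @return an `igraph` graph with edge attribute `weight` (Pearson r) and
#'   graph attribute `threshold`.
#' @export
build_correlation_network <- function(x, genes = NULL, samples = NULL,
                                      threshold = 0.6) {
  m <- expr_values(x)
  if (!is.null(genes)) m <- m[intersect(rownames(m), genes), , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (ncol(m) < 3) stop("need at least 3 samples to correlate")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  vars <- apply(m, 1L, stats::var)
  if (any(vars == 0)) {
    message(sum(vars == 0), " zero-variance gene(s) excluded from network")
    m <- m[vars > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(m))
  hit <- which(abs(cc) >= threshold & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[hit[, 1]],
                      to = rownames(m)[hit[, 2]],
                      weight = cc[hit], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(m), stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Detect expression modules by silhouette-selected k-means
#'
#' k-means on row-standardized expression profiles (10 restarts, best
#' inertia kept); k chosen over `k_range` by maximum mean silhouette
#' width (Euclidean). `k_range = 1` is allowed as an explicit single-module
#' request.
#'
#' @param x genes x samples matrix or [ws_experiment]; rows must match the
#'   network node set.
#' @param k_range candidate module counts (default `2:8`, trimmed to
#'   `n - 1`).
#' @param seed RNG seed for the restarts.
#' @return named integer vector: module id per gene.
#' @export
detect_modules <- function(x, k_range = 2:8, seed = 1) {
  m <- expr_values(x)
  if (nrow(m) < 2 && !identical(as.integer(k_range), 1L))
    stop("need at least 2 genes to partition")
  set.seed(seed)
  ctr <- m - rowMeans(m)
  sds <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  sds[sds == 0] <- 1
  z <- ctr / sds
  k_range <- k_range[k_range <= max(1, nrow(m) - 1)]
  if (identical(as.integer(k_range), 1L))
    return(stats::setNames(rep(1L, nrow(m)), rownames(m)))
  k_range <- k_range[k_range >= 2]
  if (!length(k_range)) stop("k_range has no feasible value")
  dd <- stats::dist(z)
  fits <- lapply(k_range, function(k) stats::kmeans(z, centers = k,
                                                    nstart = 10,
                                                    iter.max = 50))
  sil <- vapply(seq_along(k_range), function(i) {
    s <- cluster::silhouette(fits[[i]]$cluster, dd)
    mean(s[, "sil_width"])
  }, numeric(1))
  best <- fits[[which.max(sil)]]
  stats::setNames(as.integer(best$cluster), rownames(m))
}

#' Within-module degree z-score (Z)
#'
#' `Z_i = (kappa_i - mean_m) / sd_m`, where `kappa_i` counts node i's
#' edges into its own module m and mean/sd are over m's members
#' (population sd, as in the original cartography). Modules with zero
#' degree spread give `Z = 0` (message).
#'
#' @param g `igraph` network.
#' @param modules named module id per node (covering all nodes).
#' @return named numeric Z per node.
#' @export
within_module_degree_z <- function(g, modules) {
  nodes <- igraph::V(g)$name
  check_partition(nodes, modules)
  kappa <- within_degree(g, modules)
  z <- numeric(length(nodes))
  names(z) <- nodes
  flat <- 0L
  for (mod in unique(modules)) {
    idx <- names(modules)[modules == mod]
    mu <- mean(kappa[idx])
    sdv <- sqrt(mean((kappa[idx] - mu)^2))    # population sd
    if (is.na(sdv) || sdv == 0) {
      z[idx] <- 0
      flat <- flat + 1L
    } else {
      z[idx] <- (kappa[idx] - mu) / sdv
    }
  }
  if (flat) message(flat, " module(s) with zero degree spread: Z set to 0")
  z
}

# Edges from each node into its own module.
within_degree <- function(g, modules) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  kappa <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(el)) {
    same <- modules[el[, 1]] == modules[el[, 2]]
    tab <- table(c(el[same, 1], el[same, 2]))
    kappa[names(tab)] <- as.numeric(tab)
  }
  kappa
}

check_partition <- function(nodes, modules) {
  if (is.null(names(modules)) || !all(nodes %in% names(modules)))
    stop("`modules` must be named and cover every network node")
  invisible(TRUE)
}

#' Participation coefficient (P)
#'
#' Guimera variant: `P_i = 1 - sum_m (k_im / k_i)^2` over all modules m;
#' clusterphobic variant: `P_i = 1 - (kappa_i / k_i)^2` using only the
#' own-module degree. Isolated nodes get `P = 0`.
#'
#' @param g `igraph` network.
#' @param modules named module id per node.
#' @param variant `"guimera"` (default) or `"clusterphobic"`.
#' @return named numeric P per node, in `[0, 1]`.
#' @export
participation_coefficient <- function(g, modules,
                                      variant = c("guimera",
                                                  "clusterphobic")) {
  variant <- match.arg(variant)
  nodes <- igraph::V(g)$name
  check_partition(nodes, modules)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g)
  P <- stats::setNames(numeric(length(nodes)), nodes)
  if (variant == "clusterphobic") {
    kappa <- within_degree(g, modules)
    nz <- deg > 0
    P[nz] <- 1 - (kappa[nodes][nz] / deg[nz])^2
    return(P)
  }
  # per-node degree into each module
  mods <- sort(unique(modules))
  kim <- matrix(0, length(nodes), length(mods),
                dimnames = list(nodes, as.character(mods)))
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      kim[a, as.character(modules[b])] <- kim[a, as.character(modules[b])] + 1
      kim[b, as.character(modules[a])] <- kim[b, as.character(modules[a])] + 1
    }
  }
  nz <- deg > 0
  P[nz] <- 1 - rowSums((kim[nodes, , drop = FALSE][nz, , drop = FALSE] /
                          deg[nz])^2)
  pmin(pmax(P, 0), 1)
}

#' Average Pearson correlation with network neighbours (APCC)
#'
#' Mean of the signed correlations (edge weights) between a node and its
#' neighbours. Isolated nodes have no neighbours: APCC is `NA` (message).
#'
#' @param g `igraph` network with `weight` edge attribute holding the
#'   Pearson r.
#' @return named numeric APCC per node, in `[-1, 1]` (or `NA`).
#' @export
apcc <- function(g) {
  nodes <- igraph::V(g)$name
  w <- igraph::E(g)$weight
  el <- igraph::as_edgelist(g)
  s <- stats::setNames(numeric(length(nodes)), nodes)
  k <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      s[el[r, 1]] <- s[el[r, 1]] + w[r]
      s[el[r, 2]] <- s[el[r, 2]] + w[r]
      k[el[r, 1]] <- k[el[r, 1]] + 1
      k[el[r, 2]] <- k[el[r, 2]] + 1
    }
  }
  out <- s / k
  if (any(k == 0)) {
    message(sum(k == 0), " isolated node(s): APCC undefined")
    out[k == 0] <- NA_real_
  }
  out
}

#' Assign the seven cartography regions from (Z, P)
#'
#' Hubs have `Z >= hub_z` (default 2.5). Non-hubs: R1 `P <= 0.05`, R2
#' `0.05 < P <= 0.62`, R3 `0.62 < P <= 0.80`, R4 `P > 0.80`. Hubs: R5
#' `P <= 0.30`, R6 `0.30 < P <= 0.75`, R7 `P > 0.75`. Boundaries are
#' configurable.
#'
#' @param Z,P numeric vectors (recycled names kept from `Z`); `P` must lie
#'   in `[0, 1]`.
#' @param hub_z hub threshold on Z.
#' @param nonhub_bounds,hub_bounds increasing P boundaries for the
#'   non-hub (3 values) and hub (2 values) strips.
#' @return character vector of regions `"R1"`..`"R7"`.
#' @export
assign_region <- function(Z, P, hub_z = 2.5,
                          nonhub_bounds = c(0.05, 0.62, 0.80),
                          hub_bounds = c(0.30, 0.75)) {
  if (any(P < 0 | P > 1, na.rm = TRUE))
    stop("P must lie in [0, 1]")
  region <- character(length(Z))
  hub <- Z >= hub_z
  region[!hub] <- c("R1", "R2", "R3", "R4")[
    1L + findInterval(P[!hub], nonhub_bounds, left.open = TRUE)]
  region[hub] <- c("R5", "R6", "R7")[
    1L + findInterval(P[hub], hub_bounds, left.open = TRUE)]
  names(region) <- names(Z)
  region
}

#' Classify node roles by neighbour correlation
#'
#' `fight_club_hub` iff `APCC < 0`; `party_hub` iff `APCC > party_cutoff`;
#' `date_hub` iff `0 < APCC <= party_cutoff`; otherwise `none`. By default
#' the rule applies to all nodes; `hubs_only` restricts hub roles to nodes
#' with `Z >= hub_z`.
#'
#' @param topology data.frame with columns `APCC` and (for `hubs_only`)
#'   `Z`.
#' @param party_cutoff APCC above which a node is a party hub
#'   (default 0.5).
#' @param hubs_only restrict roles to `Z >= hub_z` nodes.
#' @param hub_z hub threshold used with `hubs_only`.
#' @return character vector of roles aligned to `topology` rows.
#' @export
classify_roles <- function(topology, party_cutoff = 0.5, hubs_only = FALSE,
                           hub_z = 2.5) {
  a <- topology$APCC
  role <- rep("none", length(a))
  role[!is.na(a) & a < 0] <- "fight_club_hub"
  role[!is.na(a) & a > 0 & a <= party_cutoff] <- "date_hub"
  role[!is.na(a) & a > party_cutoff] <- "party_hub"
  if (hubs_only) role[topology$Z < hub_z] <- "none"
  role
}

#' Mine switch genes from the cartography
#'
#' Switch genes are non-hub "kinless" nodes — region R4 (`Z < 2.5`,
#' `P > 0.80`), i.e. mostly external links — whose average neighbour
#' correlation is negative (`APCC < 0`). Definitionally a subset of the
#' fight-club classification.
#'
#' @param topology data.frame from [node_cartography()] with columns
#'   `gene_id`, `Z`, `P`, `APCC`, `region`.
#' @return data.frame of the switch genes with their `Z`, `P`, `APCC`.
#' @export
find_switch_genes <- function(topology) {
  hit <- topology$region == "R4" & !is.na(topology$APCC) &
    topology$APCC < 0
  out <- topology[hit, c("gene_id", "Z", "P", "APCC"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full heat cartography of a co-expression network
#'
#' Convenience wrapper: module detection, Z, P, APCC, region and role per
#' node, plus the switch-gene flag. Node attributes are also copied onto
#' the returned graph for [write_network()].
#'
#' @param g network from [build_correlation_network()].
#' @param x expression matrix or [ws_experiment] covering the nodes (used
#'   for module detection).
#' @param k_range,seed forwarded to [detect_modules()].
#' @param p_variant forwarded to [participation_coefficient()].
#' @param party_cutoff,hubs_only forwarded to [classify_roles()].
#' @param modules optional precomputed named module vector (skips
#'   detection).
#' @return list with `topology` (data.frame: `gene_id`, `degree`,
#'   `module`, `Z`, `P`, `APCC`, `region`, `role`, `switch`), `graph`
#'   (annotated igraph), `modules`.
#' @export
node_cartography <- function(g, x, k_range = 2:8, seed = 1,
                             p_variant = "clusterphobic",
                             party_cutoff = 0.5,
                             hubs_only = FALSE, modules = NULL) {
  nodes <- igraph::V(g)$name
  m <- expr_values(x)[nodes, , drop = FALSE]
  if (is.null(modules))
    modules <- detect_modules(m, k_range = k_range, seed = seed)
  Z <- within_module_degree_z(g, modules)
  P <- participation_coefficient(g, modules, variant = p_variant)
  A <- apcc(g)
  region <- assign_region(Z, P)
  topo <- data.frame(gene_id = nodes,
                     degree = as.numeric(igraph::degree(g)[nodes]),
                     module = as.integer(modules[nodes]),
                     Z = unname(Z[nodes]), P = unname(P[nodes]),
                     APCC = unname(A[nodes]), region = unname(region[nodes]),
                     row.names = NULL, stringsAsFactors = FALSE)
  topo$role <- classify_roles(topo, party_cutoff = party_cutoff,
                              hubs_only = hubs_only)
  sw <- find_switch_genes(topo)
  topo$switch <- topo$gene_id %in% sw$gene_id
  for (at in c("module", "Z", "P", "APCC", "region", "role"))
    g <- igraph::set_vertex_attr(g, at, value = topo[[at]])
  list(topology = topo, graph = g, modules = modules)
}
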