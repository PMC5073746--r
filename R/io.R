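#' Read an expression matrix and its sample sheet
#'
#' The expression table is tab-delimited with a `gene_id` first column and
#' one column per sample; the sample sheet is a CSV with header
#' `sample_id,genotype,treatment,timepoint,replicate`. Columns are
#' reordered to follow the design. Rows containing any missing or
#' unparseable value are dropped with a message reporting the count.
#'
#' @param path path to the expression TSV.
#' @param design_path path to the sample-sheet CSV.
#' @param linear_scale if `TRUE` the table holds linear intensities and is
#'   log2-transformed at load. Default `FALSE` (already log2).
#' @param timepoint_labels optional labels forwarded to [ws_experiment()].
#' @return a [ws_experiment].
#' @export
read_expression_matrix <- function(path, design_path, linear_scale = FALSE,
                                   timepoint_labels = NULL) {
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  id_col <- if ("gene_id" %in% names(tab)) "gene_id" else names(tab)[1]
  gene_ids <- as.character(tab[[id_col]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)])
  miss <- setdiff(design$sample_id, names(tab))
  if (length(miss))
    stop("expression table is missing sample column(s): ",
         paste(miss, collapse = ", "))
  vals <- suppressWarnings(
    vapply(design$sample_id, function(s) as.numeric(tab[[s]]),
           numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gene_ids, design$sample_id))
  bad <- !apply(vals, 1L, function(r) all(is.finite(r)))
  if (any(bad)) {
    message("dropped ", sum(bad),
            " row(s) with missing or unparseable values")
    vals <- vals[!bad, , drop = FALSE]
  }
  if (linear_scale) {
    if (any(vals <= 0))
      stop("linear-scale intensities must be positive for log2 transform")
    vals <- log2(vals)
  }
  ws_experiment(vals, design, timepoint_labels = timepoint_labels)
}

#' Write an expression matrix and its sample sheet
#'
#' @param x a [ws_experiment].
#' @param path output TSV path.
#' @param design_path optional output CSV path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path))
    utils::write.csv(x$design, design_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a term-to-gene-set mapping (two-column TSV or GMT)
#'
#' Two-column files map a term id to one gene per line; GMT lines are
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate (term, gene)
#' pairs are deduplicated. Terms are returned sorted by id with sorted
#' member sets, so the two dialects of the same content read identically.
#'
#' @param path input path.
#' @param format `"auto"` (by `.gmt` extension), `"tsv"` or `"gmt"`.
#' @return named list: term id -> character vector of gene ids.
#' @export
read_gene_term_map <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n < 3))
      stop("malformed GMT line ", which(n < 3)[1],
           ": fewer than 3 fields")
    terms <- vapply(fields, `[[`, "", 1L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    map <- stats::setNames(sets, terms)
    if (anyDuplicated(terms)) {  # merge repeated term lines
      map <- lapply(split(seq_along(terms), terms),
                    function(i) unique(unlist(sets[i])))
    }
    map <- lapply(map, as.character)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n < 2))
      stop("malformed two-column line ", which(n < 2)[1],
           ": fewer than 2 fields")
    term <- vapply(fields, `[[`, "", 1L)
    gene <- vapply(fields, `[[`, "", 2L)
    map <- lapply(split(gene, term), unique)
  }
  map <- map[order(names(map))]
  lapply(map, sort)
}

#' Write a term-to-gene-set mapping
#'
#' @param map named list of gene-id vectors.
#' @param path output path.
#' @param format `"gmt"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_term_map <- function(map, path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- vapply(names(map), function(t)
      paste(c(t, t, map[[t]]), collapse = "\t"), "")
  } else {
    lines <- unlist(lapply(names(map), function(t)
      paste(t, map[[t]], sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a co-expression network to GraphML (plus an edge-list TSV)
#'
#' Node attributes present on the graph (module, Z, P, APCC, region, role)
#' and the `weight` edge attribute (Pearson r) are written to GraphML; the
#' edge list mirrors the edges as `from<TAB>to<TAB>weight`.
#'
#' @param network an `igraph` graph as built by
#'   [build_correlation_network()], optionally annotated via
#'   [node_cartography()].
#' @param path GraphML output path.
#' @param edgelist_path optional TSV output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, edgelist_path = NULL) {
  stopifnot(inherits(network, "igraph"))
  igraph::write_graph(network, path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(network, what = "edges")
    utils::write.table(el, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML path.
#' @return an `igraph` graph.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Pipeline configuration with study defaults
#'
#' Every threshold used by the pipeline, with the study values as
#' defaults. Override any key through `...` or a YAML file via
#' [read_pipeline_config()].
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sam_fdr_percent = 0.1,     # SAM screen, percent FDR
    sam_n_perm      = 300,
    anova_alpha     = 0.01,    # Bonferroni-corrected one-way ANOVA
    ttest_p         = 0.01,    # per-timepoint Welch t threshold
    fc_threshold    = 2,       # |FC| >= 2  <=>  |dlog2| >= 1
    rws_fc_threshold = 3,      # re-watering filter FC >= 3 / <= -3
    day27_p         = 0.08,    # network input set, last timepoint
    day27_fc        = 1.7,
    stem_c          = 2,       # max unit change per step
    stem_m          = 30,      # model profiles retained
    stem_alpha      = 0.05,    # Bonferroni over m profiles
    network_threshold = 0.6,   # |r| edge cutoff
    p_variant       = "clusterphobic",  # kinless R4 on external-link share
    hub_z           = 2.5,
    region_p_bounds = list(nonhub = c(0.05, 0.62, 0.80),
                           hub    = c(0.30, 0.75)),
    party_cutoff    = 0.5,     # APCC above -> party hub
    enrich_alpha    = 0.01,    # leaves; berries use 0.05
    enrich_correction = "none",
    linear_scale    = FALSE
  )
  utils::modifyList(cfg, list(...))
}

#' Read a YAML pipeline configuration
#'
#' Keys absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML path.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  utils::modifyList(pipeline_config(), user)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
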