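#' Water-stress expression experiment
#'
#' Container pairing a genes x samples matrix of log2 intensities with a
#' sample design (genotype, treatment, timepoint, replicate). All pipeline
#' stages take this object or a plain matrix.
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns, log2 intensity scale, all values finite.
#' @param design data.frame with columns `sample_id`, `genotype`,
#'   `treatment` (one of `WW`, `WS`, `RWS`), `timepoint` (ordinal index
#'   starting at 0) and `replicate` (positive integer). One row per column
#'   of `values`; `(genotype, treatment, timepoint, replicate)` tuples must
#'   be unique.
#' @param timepoint_labels optional vector labelling the ordinal timepoints
#'   (e.g. days after stress imposition, `c(2, 6, 27)`).
#'
#' @return An object of class `ws_experiment`: a list with elements
#'   `values`, `design` and `timepoint_labels`. Columns of `values` are
#'   reordered to follow the design.
#' @export
ws_experiment <- function(values, design, timepoint_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("`values` must carry gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  required <- c("sample_id", "genotype", "treatment", "timepoint", "replicate")
  miss <- setdiff(required, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[required]
  design$sample_id <- as.character(design$sample_id)
  design$genotype  <- as.character(design$genotype)
  design$treatment <- as.character(design$treatment)
  design$timepoint <- as.integer(design$timepoint)
  design$replicate <- as.integer(design$replicate)
  if (!all(design$treatment %in% c("WW", "WS", "RWS")))
    stop("treatment must be one of WW, WS, RWS")
  if (any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  key <- do.call(paste, c(design[c("genotype", "treatment",
                                   "timepoint", "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (genotype, treatment, timepoint, replicate) tuple")
  if (ncol(values) != nrow(design))
    stop("matrix has ", ncol(values), " columns but design has ",
         nrow(design), " samples")
  if (is.null(colnames(values))) {
    colnames(values) <- design$sample_id
  } else {
    miss <- setdiff(design$sample_id, colnames(values))
    if (length(miss))
      stop("expression matrix is missing sample column(s): ",
           paste(miss, collapse = ", "))
    values <- values[, design$sample_id, drop = FALSE]
  }
  if (!all(is.finite(values)))
    stop("values must be finite; drop or impute rows at load")
  structure(list(values = values, design = design,
                 timepoint_labels = timepoint_labels),
            class = "ws_experiment")
}

#' @export
print.ws_experiment <- function(x, ...) {
  d <- x$design
  cat("ws_experiment: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  genotypes: ", paste(sort(unique(d$genotype)), collapse = ", "),
      " | treatments: ", paste(sort(unique(d$treatment)), collapse = ", "),
      " | timepoints: ", paste(sort(unique(d$timepoint)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.ws_experiment <- function(x) dim(x$values)

#' Select sample ids from an experiment design
#'
#' @param x a [ws_experiment].
#' @param genotype,treatment,timepoint optional filters; `NULL` keeps all.
#' @return character vector of sample ids, in design order.
#' @export
samples_for <- function(x, genotype = NULL, treatment = NULL,
                        timepoint = NULL) {
  stopifnot(inherits(x, "ws_experiment"))
  d <- x$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(genotype))  keep <- keep & d$genotype %in% genotype
  if (!is.null(treatment)) keep <- keep & d$treatment %in% treatment
  if (!is.null(timepoint)) keep <- keep & d$timepoint %in% timepoint
  d$sample_id[keep]
}

# Internal: accept a ws_experiment or a plain matrix.
expr_values <- function(x) {
  if (inherits(x, "ws_experiment")) x$values else {
    m <- as.matrix(x)
    if (is.null(rownames(m)) && nrow(m) > 0)
      rownames(m) <- paste0("g", seq_len(nrow(m)))
    m
  }
}
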