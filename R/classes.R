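#' Assemble an expression study
#'
#' Bundles a gene x sample count matrix with per-sample condition and
#' source-database labels and per-gene lengths, the common input of the
#' differential-expression and latent-projection signature routes.
#'
#' @param counts integer-like gene x sample matrix with gene ids as row names
#'   and sample ids as column names.
#' @param gene_lengths per-gene lengths in kilobases, in row order of
#'   `counts`.
#' @param condition per-sample factor (or character) with levels
#'   `control`/`tumor`.
#' @param database per-sample factor (or character) naming the originating
#'   database (e.g. the batch of a compendium), used as a model covariate.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(counts, gene_lengths, condition, database) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  n <- ncol(counts)
  if (length(condition) != n || length(database) != n)
    stop("length of 'condition' and 'database' must equal ncol(counts)")
  if (length(gene_lengths) != nrow(counts))
    stop("length of 'gene_lengths' must equal nrow(counts)")
  if (any(gene_lengths <= 0)) stop("'gene_lengths' must be positive")
  condition <- factor(condition, levels = c("control", "tumor"))
  if (anyNA(condition)) stop("'condition' must use levels control/tumor")
  structure(
    list(counts = counts,
         gene_lengths = setNames(as.numeric(gene_lengths), rownames(counts)),
         condition = condition,
         database = factor(database)),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%d tumor, %d control; %d database(s))\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "tumor"), sum(x$condition == "control"),
              nlevels(x$database)))
  invisible(x)
}

#' Construct a gene signature
#'
#' A disease-associated gene signature is a pair of disjoint ordered gene-id
#' lists (up- and down-regulated in disease relative to control), together
#' with the eligibility universe and a provenance label naming the route that
#' built it.
#'
#' @param up,down ordered character vectors of gene ids; must be disjoint.
#' @param method provenance label, e.g. `"moderated_lm"`, `"nb_glm"` or
#'   `"transfer_learning"`.
#' @param universe gene-id set the signature was restricted to.
#' @param truncated logical flag set when fewer eligible genes existed than
#'   the requested minimum.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up, down, method = "unspecified",
                           universe = union(up, down), truncated = FALSE) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)) > 0)
    stop("'up' and 'down' gene sets must be disjoint")
  if (!all(c(up, down) %in% universe))
    stop("signature genes must be contained in 'universe'")
  structure(list(up = up, down = down, method = method,
                 universe = as.character(universe), truncated = truncated),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature [%s]: %d up, %d down (universe %d genes)%s\n",
              x$method, length(x$up), length(x$down), length(x$universe),
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Construct a perturbation reference
#'
#' A drug x gene matrix of modified z-scores for a single cell line: the
#' search space of signature reversion and the basis of cosine drug-drug
#' similarity.
#'
#' @param z drug x gene numeric matrix with drug ids as row names and gene
#'   ids as column names; all values finite.
#' @param cell_line label of the profiled cell line.
#' @return An object of class `perturbation_reference`.
#' @export
perturbation_reference <- function(z, cell_line = "unknown") {
  z <- as.matrix(z)
  if (is.null(rownames(z)) || is.null(colnames(z)))
    stop("'z' must have drug row names and gene column names")
  if (anyDuplicated(rownames(z)) || anyDuplicated(colnames(z)))
    stop("drug and gene ids must be unique")
  if (!all(is.finite(z))) stop("'z' must be finite")
  structure(list(z = z, cell_line = cell_line,
                 drug_ids = rownames(z), gene_ids = colnames(z)),
            class = "perturbation_reference")
}

#' @export
print.perturbation_reference <- function(x, ...) {
  cat(sprintf("perturbation_reference: %d drugs x %d genes (cell line %s)\n",
              nrow(x$z), ncol(x$z), x$cell_line))
  invisible(x)
}

#' Construct a drug annotation table
#'
#' @param drugs data.frame with columns `drug_id`, `fda_approved` (logical),
#'   `in_trial` (logical; trial membership for the studied disease) and
#'   `moa` (mechanism-of-action label).
#' @param targets named list mapping drug id to a character vector of target
#'   gene ids.
#' @param fingerprints logical drug x bit matrix of structure fingerprints.
#' @param viability drug x cell-line numeric matrix of median log2 viability
#'   fold changes (may contain `NA` for unassayed pairs).
#' @param disease label of the disease the annotations refer to.
#' @return An object of class `drug_annotations`.
#' @export
drug_annotations <- function(drugs, targets = list(), fingerprints = NULL,
                             viability = NULL, disease = "disease") {
  stopifnot(is.data.frame(drugs),
            all(c("drug_id", "fda_approved", "in_trial") %in% names(drugs)))
  if (anyDuplicated(drugs$drug_id)) stop("drug ids must be unique")
  if (!is.null(fingerprints) &&
      !identical(rownames(fingerprints), drugs$drug_id))
    stop("fingerprint rows must match drug ids")
  structure(list(drugs = drugs, targets = targets,
                 fingerprints = fingerprints, viability = viability,
                 disease = disease),
            class = "drug_annotations")
}

#' @export
print.drug_annotations <- function(x, ...) {
  cat(sprintf("drug_annotations [%s]: %d drugs (%d FDA-approved, %d in trial)\n",
              x$disease, nrow(x$drugs), sum(x$drugs$fda_approved),
              sum(x$drugs$in_trial)))
  invisible(x)
}
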