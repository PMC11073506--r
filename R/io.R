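# Plain-text readers and writers for the formats the pipeline exchanges:
# GCT v1.3 matrices, GMT gene-set files, and TSV tables.

#' Write a matrix as GCT v1.3
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file.
#' @export
write_gct <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t0\t0", nrow(mat), ncol(mat)), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  body <- cbind(rownames(mat), format(mat, trim = TRUE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
}

#' Read a GCT v1.3 matrix
#'
#' @param path GCT file (version 1.3, no row/column metadata).
#' @return Numeric matrix with row and column names.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1L], "#1.3"))
    stop("not a GCT 1.3 file: ", path)
  dims <- as.integer(strsplit(header[2L], "\t")[[1L]])
  if (dims[3L] != 0 || dims[4L] != 0)
    stop("GCT row/column metadata not supported")
  tab <- read.delim(path, skip = 2L, check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  if (!identical(dim(mat), dims[1:2]))
    stop("GCT dimensions do not match the header")
  mat
}

#' Write gene signatures as a GMT file
#'
#' Each signature contributes two lines, `<name>_UP` and `<name>_DN`.
#'
#' @param sigs named list of [gene_signature()] objects (names become set
#'   name prefixes).
#' @param path output file.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(signature = sigs)
  lines <- unlist(lapply(names(sigs), function(nm) {
    s <- sigs[[nm]]
    c(paste(c(paste0(nm, "_UP"), s$method, s$up), collapse = "\t"),
      paste(c(paste0(nm, "_DN"), s$method, s$down), collapse = "\t"))
  }))
  writeLines(lines, path)
}

#' Read a GMT file
#'
#' @param path GMT file.
#' @return Named list of character vectors (set name to gene ids); the
#'   second (description) field is kept as attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write the full synthetic benchmark to a directory
#'
#' Emits the counts, sample metadata, gene lengths, loadings, perturbation
#' reference (GCT 1.3), annotations, fingerprints (hex bitstrings),
#' viability table and ground truth (JSON) as plain-text files.
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wt <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(data.frame(gene = rownames(sim$study$counts), sim$study$counts,
                check.names = FALSE), "counts.tsv")
  wt(data.frame(sample_id = colnames(sim$study$counts),
                condition = as.character(sim$study$condition),
                database = as.character(sim$study$database)),
     "sample_metadata.tsv")
  wt(data.frame(gene = names(sim$study$gene_lengths),
                length_kb = unname(sim$study$gene_lengths)),
     "gene_lengths.tsv")
  wt(data.frame(gene = rownames(sim$loadings), sim$loadings,
                check.names = FALSE), "loadings.tsv")
  write_gct(sim$reference$z, p("perturbation_reference.gct"))
  wt(sim$annotations$drugs, "drug_annotations.tsv")
  fp <- sim$annotations$fingerprints
  hex <- apply(fp, 1, function(bits)
    paste(sprintf("%02x", colSums(matrix(as.integer(bits), nrow = 8) *
                                    2^(7:0))), collapse = ""))
  wt(data.frame(drug_id = rownames(fp), fingerprint_hex = hex),
     "fingerprints.tsv")
  wt(data.frame(drug_id = rownames(sim$annotations$viability),
                sim$annotations$viability, check.names = FALSE),
     "viability.tsv")
  jsonlite::write_json(sim$truth, p("ground_truth.json"), auto_unbox = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Write a differential result as TSV
#'
#' @param de a `differential_result`.
#' @param path output file.
#' @export
write_differential_result <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Write a connectivity table as TSV
#'
#' @param ct a `connectivity_table`.
#' @param path output file.
#' @param candidates optional candidate drug ids; adds a `pass_filter`
#'   column.
#' @export
write_connectivity_table <- function(ct, path, candidates = NULL) {
  df <- as.data.frame(ct)
  if (!is.null(candidates)) df$pass_filter <- df$drug %in% candidates
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
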