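#' UMI count matrix with sample labels and gene flags
#'
#' Lightweight container for an integer genes x cells UMI matrix together
#' with gene identifiers, cell barcodes, a per-cell sample label, and gene
#' flags: mitochondrial genes (symbol prefix `MT-`, case-insensitive, or a
#' user-supplied list) and exogenous tag genes (by configured names).
#' Counts are stored as a sparse `dgCMatrix`.
#'
#' @param counts integer matrix or sparse Matrix, genes in rows.
#' @param gene_ids character vector of gene identifiers (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param sample sample label per cell (single value recycled, or one per
#'   cell).
#' @param tag_genes character vector of tag gene names (may be absent from
#'   `gene_ids`).
#' @param mito_genes optional explicit list of mitochondrial gene ids; by
#'   default any id starting with `MT-` (case-insensitive).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `barcodes`, `sample`, `is_mito`, `is_tag`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes, sample = "S1",
                         tag_genes = character(0), mito_genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    bad <- which(vals < 0 | vals != round(vals))[1]
    stop(sprintf("counts must be nonnegative integers (offending value %g)",
                 vals[bad]))
  }
  if (nrow(counts) != length(gene_ids)) {
    stop("gene_ids length does not match the number of rows")
  }
  if (ncol(counts) != length(barcodes)) {
    stop("barcodes length does not match the number of columns")
  }
  if (anyDuplicated(barcodes)) {
    stop(sprintf("duplicate barcode: %s", barcodes[duplicated(barcodes)][1]))
  }
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1]))
  }
  sample <- as.character(sample)
  if (length(sample) == 1) sample <- rep(sample, length(barcodes))
  if (length(sample) != length(barcodes)) {
    stop("sample must have one label per cell")
  }
  is_mito <- if (is.null(mito_genes)) {
    grepl("^MT-", gene_ids, ignore.case = TRUE)
  } else {
    gene_ids %in% mito_genes
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 sample = sample, is_mito = is_mito,
                 is_tag = gene_ids %in% tag_genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d sample(s), %d mito gene(s), %d tag gene(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$sample)),
              sum(x$is_mito), sum(x$is_tag)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells (and optionally genes)
#'
#' @param x a [count_matrix()].
#' @param cells logical/integer/character index of cells to keep.
#' @param genes optional index of genes to keep.
#' @return A [count_matrix()].
#' @export
subset_cells <- function(x, cells, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.character(cells)) cells <- match(cells, x$barcodes)
  keep_g <- if (is.null(genes)) seq_along(x$gene_ids) else genes
  count_matrix(x$counts[keep_g, cells, drop = FALSE],
               gene_ids = x$gene_ids[keep_g],
               barcodes = x$barcodes[cells],
               sample = x$sample[cells],
               tag_genes = x$gene_ids[keep_g][x$is_tag[keep_g]],
               mito_genes = x$gene_ids[keep_g][x$is_mito[keep_g]])
}

#' Read a UMI count matrix
#'
#' Reads either a 10x-style Matrix Market triplet (a directory holding
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv`; tab-separated, no header)
#' or a dense CSV (genes in rows, first column the gene id, header row of
#' barcodes). Counts must be nonnegative integers; violations and dimension
#' mismatches raise a format error naming the offending record.
#'
#' @param path directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`; guessed from `path` when missing.
#' @param sample sample label(s) for the cells (default `"S1"`).
#' @param tag_genes tag gene names used to set the `is_tag` flag.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx", "csv"), sample = "S1",
                              tag_genes = character(0)) {
  if (length(format) > 1) {
    format <- if (dir.exists(path)) "mtx" else "csv"
  }
  format <- match.arg(format, c("mtx", "csv"))
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) {
      if (!file.exists(f)) stop(sprintf("missing file: %s", f))
    }
    m <- Matrix::readMM(mtx)
    features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != nrow(features)) {
      stop(sprintf("matrix has %d rows but features.tsv has %d records",
                   nrow(m), nrow(features)))
    }
    if (ncol(m) != length(barcodes)) {
      stop(sprintf("matrix has %d columns but barcodes.tsv has %d records",
                   ncol(m), length(barcodes)))
    }
    count_matrix(m, gene_ids = features[[1]], barcodes = barcodes,
                 sample = sample, tag_genes = tag_genes)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("dense CSV contains non-numeric entries")
    count_matrix(m, gene_ids = gene_ids, barcodes = colnames(df)[-1],
                 sample = sample, tag_genes = tag_genes)
  }
}

#' Write a UMI count matrix
#'
#' Inverse of [read_count_matrix()]; round-trips are lossless for both
#' formats.
#'
#' @param x a [count_matrix()].
#' @param path output directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    m <- x$counts
    dimnames(m) <- NULL
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = x$gene_ids, name = x$gene_ids, type = "Gene Expression"),
      file.path(path, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(bc = x$barcodes),
                       file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    df <- data.frame(gene = x$gene_ids, as.matrix(x$counts),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", x$barcodes)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0),
#' the total UMI count, and the mitochondrial fraction (share of counts on
#' `MT-` flagged genes). Cells with zero total counts get an undefined
#' (`NA`) mitochondrial fraction and are flagged `degenerate` for removal;
#' no division by zero is performed.
#'
#' @param x a [count_matrix()].
#' @return Data frame: barcode, sample, n_detected, total_counts,
#'   mito_fraction, degenerate.
#' @export
compute_cell_qc <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  total <- Matrix::colSums(x$counts)
  n_det <- Matrix::colSums(x$counts > 0)
  mito <- Matrix::colSums(x$counts[x$is_mito, , drop = FALSE])
  frac <- ifelse(total > 0, mito / total, NA_real_)
  data.frame(barcode = x$barcodes, sample = x$sample,
             n_detected = as.integer(n_det),
             total_counts = as.numeric(total),
             mito_fraction = frac,
             degenerate = total == 0,
             stringsAsFactors = FALSE)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with strictly more than `min_genes` detected
#' genes and a mitochondrial fraction of at most `max_mito`: a cell with
#' exactly `min_genes` detected genes is removed, a cell at exactly
#' `max_mito` is retained. Degenerate (zero-count) cells are always removed.
#' The returned matrix carries a `removed` attribute with per-sample removal
#' counts.
#'
#' @param x a [count_matrix()].
#' @param qc output of [compute_cell_qc()]; recomputed when `NULL`.
#' @param min_genes detected-genes threshold (default 1250).
#' @param max_mito mitochondrial-fraction threshold (default 0.25).
#' @return Filtered [count_matrix()] with attribute `removed` (named
#'   integer vector, cells removed per sample).
#' @export
filter_cells <- function(x, qc = NULL, min_genes = 1250, max_mito = 0.25) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(qc)) qc <- compute_cell_qc(x)
  if (!identical(qc$barcode, x$barcodes)) {
    stop("qc table is not aligned with the matrix")
  }
  keep <- !qc$degenerate & qc$n_detected > min_genes &
    !is.na(qc$mito_fraction) & qc$mito_fraction <= max_mito
  removed <- tapply(!keep, x$sample, sum)
  out <- subset_cells(x, which(keep))
  attr(out, "removed") <- removed
  out
}

#' Library-size normalization with log transform
#'
#' Produces the normalized expression layer used by correlation and
#' differential expression: each count is divided by the cell's total,
#' scaled to 10,000 transcripts per cell, and natural-log transformed as
#' `ln(1 + 10000 * x / total)`. Zero counts map to exactly zero; raw counts
#' are untouched (bursting inference always consumes raw counts). A cell
#' with zero total counts reaching this stage is a contract violation.
#'
#' @param x a [count_matrix()] of QC-passed cells.
#' @param scale_factor transcripts-per-cell scale (default 10000).
#' @return A sparse `dgCMatrix` (genes x cells) of normalized values, with
#'   dimnames from the input.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "count_matrix"))
  total <- Matrix::colSums(x$counts)
  if (any(total == 0)) {
    stop("cell with zero total counts reached normalization; filter cells first")
  }
  norm <- x$counts %*% Matrix::Diagonal(x = scale_factor / total)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(x$counts)
  methods::as(norm, "CsparseMatrix")
}
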