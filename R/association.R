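#' Cells with nonzero expression of any tag
#'
#' Selects the cells whose raw count is positive for at least one of the
#' exogenous tag genes (Dendra2 / HaloTag analogues); these proxy cells
#' with detectable ectopic Pol II expression.
#'
#' @param x a [count_matrix()].
#' @param tag_genes tag gene names; each must be present in the matrix.
#' @return Character vector of barcodes.
#' @export
select_tag_positive_cells <- function(x, tag_genes) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(tag_genes, x$gene_ids)
  if (length(missing) > 0) {
    stop(sprintf("tag gene not present in matrix: %s", missing[1]))
  }
  sub <- x$counts[match(tag_genes, x$gene_ids), , drop = FALSE]
  x$barcodes[Matrix::colSums(sub > 0) > 0]
}

# Vectorized Pearson correlation of every row of `m` against vector `v`,
# with the t-transform two-sided p value on n - 2 degrees of freedom.
.row_cor_test <- function(m, v) {
  n <- length(v)
  v_c <- v - mean(v)
  sv <- sqrt(sum(v_c^2))
  rm_ <- Matrix::rowMeans(m)
  cross <- as.numeric(m %*% v_c)                     # sum(x * v_c), means cancel
  ss <- as.numeric(Matrix::rowSums(m^2)) - n * rm_^2 # sum((x - mean)^2)
  ss[ss < 0] <- 0
  r <- cross / (sqrt(ss) * sv)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  list(r = r, p = p, var_zero = ss == 0)
}

#' Genome-wide correlation with a tag gene
#'
#' Pearson correlation of every gene's normalized expression with the
#' normalized expression of one tag gene across the analysis cells, with a
#' two-sided p value from the t transform (`n - 2` d.f.) and
#' Benjamini-Hochberg step-up adjustment. Genes with no expression in any
#' analysis cell are removed before testing; genes that are expressed but
#' have zero variance are dropped as undefined, with the reason recorded
#' in the `dropped` attribute. A tag vector without variance (e.g. all
#' zeros) is an error.
#'
#' @param norm normalized matrix (genes x cells) as from
#'   [normalize_counts()], with gene ids as rownames.
#' @param tag_gene name of the tag gene row.
#' @param cells optional barcodes restricting the analysis (e.g. the
#'   tag-positive cells from [select_tag_positive_cells()]); default all.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return Data frame (gene, r, p, q, significant), tag gene excluded,
#'   sorted by input gene order; attribute `dropped` names zero-variance
#'   genes.
#' @export
tag_correlation <- function(norm, tag_gene, cells = NULL, alpha = 0.05) {
  if (!tag_gene %in% rownames(norm)) {
    stop(sprintf("tag gene not present in matrix: %s", tag_gene))
  }
  if (!is.null(cells)) norm <- norm[, cells, drop = FALSE]
  v <- as.numeric(norm[tag_gene, ])
  if (stats::var(v) == 0) {
    stop(sprintf("tag gene '%s' has no variance over the analysis cells", tag_gene))
  }
  m <- norm[setdiff(rownames(norm), tag_gene), , drop = FALSE]
  expressed <- as.numeric(Matrix::rowSums(m != 0)) > 0
  m <- m[expressed, , drop = FALSE]
  ct <- .row_cor_test(m, v)
  keep <- !ct$var_zero
  dropped <- rownames(m)[!keep]
  out <- data.frame(gene = rownames(m)[keep], r = ct$r[keep], p = ct$p[keep],
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  attr(out, "dropped") <- dropped
  out
}

# Smallest positive normalized double; p values below it are clamped so
# that log-scale plots and Bonferroni products stay finite.
.p_floor <- 2.225074e-308

#' Wilcoxon differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalized expression
#' between two disjoint cell groups, with a log2 fold change computed on
#' de-logged normalized means (`log2((mean(expm1 xA) + eps) /
#' (mean(expm1 xB) + eps))`, pseudocount `eps = 1e-9`). P values are
#' floored at `2.225074e-308` before Bonferroni adjustment over the genes
#' tested; a gene is called significant when `|log2fc| >= lfc_min` and the
#' adjusted p is below `alpha`.
#'
#' @param norm normalized matrix (genes x cells) with gene ids as rownames.
#' @param cells_a,cells_b barcodes of the two groups (nonempty, disjoint).
#' @param lfc_min fold-change threshold on `|log2fc|` (default 0.5).
#' @param alpha significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @param eps pseudocount in the fold change (default 1e-9).
#' @return Data frame: gene, log2fc, p, p_adj, significant, direction
#'   (`up` when group A is higher).
#' @export
differential_expression <- function(norm, cells_a, cells_b, lfc_min = 0.5,
                                    alpha = 0.05, eps = 1e-9) {
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop("both groups must be nonempty")
  }
  if (length(intersect(cells_a, cells_b)) > 0) {
    stop("cell groups must be disjoint")
  }
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  genes <- rownames(norm)
  log2fc <- log2((rowMeans(expm1(a)) + eps) / (rowMeans(expm1(b)) + eps))
  p <- vapply(seq_along(genes), function(g) {
    if (all(a[g, ] == a[g, 1]) && all(b[g, ] == b[g, 1]) &&
        a[g, 1] == b[g, 1]) return(1)  # identical constant groups
    suppressWarnings(stats::wilcox.test(a[g, ], b[g, ])$p.value)
  }, numeric(1))
  p <- pmax(p, .p_floor)
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(gene = genes, log2fc = log2fc, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out$significant <- abs(out$log2fc) >= lfc_min & out$p_adj < alpha
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", "none"))
  rownames(out) <- NULL
  out
}

#' Gene-set (LLPS) enrichment of a significant gene list
#'
#' Two-sided Fisher's exact test on the 2x2 table crossing membership in
#' the significant set with membership in the gene set (e.g. LLPS-related
#' genes), within the tested universe. The odds ratio is the sample odds
#' ratio, with a Haldane 0.5 correction when any cell is zero; the p value
#' is Bonferroni-adjusted across `n_contrasts` tested contrasts. An empty
#' significant set carries no information and is reported with `p = 1`.
#'
#' @param significant_genes character vector, subset of `universe`.
#' @param gene_set character vector; intersected with `universe`.
#' @param universe all genes tested in the contrast (nonempty).
#' @param n_contrasts Bonferroni factor across contrasts (default 1).
#' @return List with `table` (2x2 matrix), `odds_ratio`, `p`, `p_adj`.
#' @export
llps_enrichment <- function(significant_genes, gene_set, universe,
                            n_contrasts = 1) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  sig <- intersect(significant_genes, universe)
  set <- intersect(gene_set, universe)
  a <- length(intersect(sig, set))
  b <- length(setdiff(sig, set))
  cc <- length(setdiff(set, sig))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("sig", "not_sig"), c("in_set", "out_set")))
  if (length(sig) == 0 || length(set) == 0 || length(set) == length(universe)) {
    p <- 1
    or <- NA_real_
  } else {
    p <- stats::fisher.test(tab)$p.value
    if (any(tab == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (b * cc)
    }
  }
  list(table = tab, odds_ratio = or, p = p,
       p_adj = min(1, n_contrasts * p))
}

#' Read a gene set from a plain-text file
#'
#' One gene symbol per line; blank lines ignored.
#'
#' @param path file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
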