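# mRNA-protein abundance integration: per-gene and per-sample rank
# correlation with a joint-coverage rule, and cell-type enrichment calls on
# expression matrices with the standard thresholds (BH-adjusted p < .01 and
# |log2 fold change| > 1 after a CPM < 0.01 prefilter).

#' Read an expression matrix from TSV
#'
#' Rows are genes/proteins, columns are cell types (header row), values are
#' abundances (TPM or LFQ); empty cells and `NA` are missing values.
#'
#' @param path TSV path with row identifiers in the first column.
#' @return numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_column name of the identifier column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average protein replicates into one column per cell type
#'
#' Protein quantification matrices carry one column per cell type x replicate
#' named `<cell_type>.r<k>`; analysis uses the per-cell-type average (missing
#' replicates are dropped from the mean; a cell type with no observed
#' replicate is missing).
#'
#' @param mat protein matrix with replicate columns.
#' @return matrix with one column per cell type.
#' @export
average_replicates <- function(mat) {
  ct <- sub("\\.r[0-9]+$", "", colnames(mat))
  cts <- unique(ct)
  out <- vapply(cts, function(x) {
    rowMeans(mat[, ct == x, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, cts))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(mat)
  out
}

cor_one <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(c(NA_real_, NA_real_))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
  if (method == "spearman") {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  } else {
    ct <- suppressWarnings(cor.test(log2(x + 1e-9), log2(y + 1e-9),
                                    method = "pearson"))
  }
  c(unname(ct$estimate), ct$p.value)
}

#' Per-gene mRNA-protein correlation with a joint-coverage rule
#'
#' For every gene present in both matrices, computes a rank (Spearman)
#' correlation over the cell types where both an mRNA and a protein value are
#' observed. Genes with joint coverage below `min_joint_fraction` of the cell
#' types are excluded (the boundary is inclusive: exactly 25% joint coverage
#' is kept); zero-variance genes are excluded with a note. The summary
#' reports, over included genes, the fraction with a positive coefficient,
#' the fraction with a significant positive correlation (two-sided p < 0.05
#' and positive coefficient) and the mean coefficient.
#'
#' @param mrna_matrix gene x cell-type TPM matrix.
#' @param protein_matrix protein x cell-type LFQ matrix (replicates already
#'   averaged; see [average_replicates()]); rows matched to genes by name.
#' @param min_joint_fraction coverage rule (default 0.25).
#' @param method `"spearman"` (default) or `"pearson_log"` for a linear
#'   correlation on log-transformed values.
#' @return list with `results` (id, coefficient, p_value, n_joint, included,
#'   note) and `summary` (n_included, fraction_positive,
#'   fraction_significant_positive, mean_coefficient).
#' @export
correlate_genes <- function(mrna_matrix, protein_matrix,
                            min_joint_fraction = 0.25,
                            method = c("spearman", "pearson_log")) {
  method <- match.arg(method)
  genes <- intersect(rownames(mrna_matrix), rownames(protein_matrix))
  cols <- intersect(colnames(mrna_matrix), colnames(protein_matrix))
  n_ct <- length(cols)
  res <- data.frame(id = genes, coefficient = NA_real_, p_value = NA_real_,
                    n_joint = NA_integer_, included = FALSE, note = "")
  for (k in seq_along(genes)) {
    x <- mrna_matrix[genes[k], cols]
    y <- protein_matrix[genes[k], cols]
    joint <- sum(is.finite(x) & is.finite(y))
    res$n_joint[k] <- joint
    if (joint / n_ct < min_joint_fraction) {
      res$note[k] <- "below_joint_coverage"
      next
    }
    cp <- cor_one(x, y, method)
    if (is.na(cp[1])) {
      res$note[k] <- "zero_variance"
      next
    }
    res$coefficient[k] <- cp[1]
    res$p_value[k] <- cp[2]
    res$included[k] <- TRUE
  }
  inc <- res[res$included, , drop = FALSE]
  summary <- list(
    n_included = nrow(inc),
    fraction_positive = mean(inc$coefficient > 0),
    fraction_significant_positive = mean(inc$coefficient > 0 &
                                           inc$p_value < 0.05),
    mean_coefficient = mean(inc$coefficient)
  )
  list(results = res, summary = summary)
}

#' Per-sample mRNA-protein correlation
#'
#' Rank correlation per cell type (column) across the genes shared by the two
#' matrices, with pairwise deletion of missing values.
#'
#' @inheritParams correlate_genes
#' @return data.frame with columns `cell_type`, `coefficient`, `p_value`,
#'   `n_genes`.
#' @export
correlate_samples <- function(mrna_matrix, protein_matrix,
                              method = c("spearman", "pearson_log")) {
  method <- match.arg(method)
  genes <- intersect(rownames(mrna_matrix), rownames(protein_matrix))
  cols <- intersect(colnames(mrna_matrix), colnames(protein_matrix))
  out <- lapply(cols, function(cc) {
    x <- mrna_matrix[genes, cc]
    y <- protein_matrix[genes, cc]
    cp <- cor_one(x, y, method)
    data.frame(cell_type = cc, coefficient = cp[1], p_value = cp[2],
               n_genes = sum(is.finite(x) & is.finite(y)))
  })
  do.call(rbind, out)
}

#' Cell-type enrichment calls on an expression matrix
#'
#' Genes with expression below `cpm_floor` in every column are removed; for
#' each group, a one-vs-rest log2 fold change (on group means with a
#' pseudocount) and a rank-based two-sample (Wilcoxon) p-value are computed
#' per gene, p-values are Benjamini-Hochberg adjusted across genes within the
#' group comparison, and a gene is called enriched when the adjusted p is
#' below `p_cutoff` and |log2 fold change| exceeds `lfc_cutoff`. The Wilcoxon
#' test is a deliberate lightweight surrogate for a count-model differential
#' test; externally computed fold-change/p tables can be thresholded with
#' [apply_enrichment_thresholds()] instead.
#'
#' @param mat gene x sample expression matrix.
#' @param groups character vector of group labels, one per column of `mat`
#'   (or named by column).
#' @param cpm_floor prefilter floor (default 0.01).
#' @param p_cutoff adjusted-p threshold (default 0.01).
#' @param lfc_cutoff absolute log2-fold-change threshold (default 1).
#' @param pseudocount added to group means before the ratio (default 0.01).
#' @return data.frame with one row per gene x group: `gene`, `group`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `enriched`, `flagged`
#'   (single-column group: fold change only, p missing).
#' @export
call_enriched <- function(mat, groups, cpm_floor = 0.01, p_cutoff = 0.01,
                          lfc_cutoff = 1, pseudocount = 0.01) {
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  keep <- apply(mat, 1, function(x) any(x >= cpm_floor, na.rm = TRUE))
  mat <- mat[keep, , drop = FALSE]
  out <- list()
  for (g in unique(groups)) {
    in_g <- groups == g
    single <- sum(in_g) < 2
    lfc <- log2((rowMeans(mat[, in_g, drop = FALSE], na.rm = TRUE) +
                   pseudocount) /
                (rowMeans(mat[, !in_g, drop = FALSE], na.rm = TRUE) +
                   pseudocount))
    if (single) {
      p <- rep(NA_real_, nrow(mat))
    } else {
      p <- vapply(seq_len(nrow(mat)), function(i) {
        suppressWarnings(wilcox.test(mat[i, in_g], mat[i, !in_g])$p.value)
      }, numeric(1))
    }
    padj <- p.adjust(p, method = "BH")
    out[[g]] <- data.frame(
      gene = rownames(mat), group = g, log2_fold_change = unname(lfc),
      p_value = p, adjusted_p = padj,
      enriched = !is.na(padj) & padj < p_cutoff & abs(lfc) > lfc_cutoff,
      flagged = single
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the enrichment thresholds to an external fold-change/p table
#'
#' @param table data.frame with `log2_fold_change` and `adjusted_p` columns.
#' @param p_cutoff,lfc_cutoff thresholds (defaults 0.01 and 1).
#' @return `table` with an `enriched` column added.
#' @export
apply_enrichment_thresholds <- function(table, p_cutoff = 0.01,
                                        lfc_cutoff = 1) {
  table$enriched <- !is.na(table$adjusted_p) & table$adjusted_p < p_cutoff &
    abs(table$log2_fold_change) > lfc_cutoff
  table
}
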