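#' Assemble harmonized count matrices into a 4-way expression tensor
#'
#' Places every count into a gene x tissue x treatment x replicate array by
#' axis label, so the result is independent of the order in which the
#' matrices are supplied.  Every (tissue, treatment, replicate) cell of the
#' grid must be covered exactly once.
#'
#' @param matrices list of [count_matrix] objects sharing one gene order
#'   (see [harmonize_genes()]).
#' @param sample_map a [sample_map] defining the treatment/replicate grid.
#' @return an object of class `expression_tensor`: list with `values`
#'   (4-way array with dimnames), `standardized` flag and a `log_transform`
#'   record (filled by [standardize_tensor()]).
#' @export
assemble_tensor <- function(matrices, sample_map) {
  stopifnot(length(matrices) >= 1)
  genes <- matrices[[1]]$gene_ids
  for (m in matrices)
    if (!identical(m$gene_ids, genes))
      stop("matrices do not share one gene order; run harmonize_genes() first")
  tissues <- vapply(matrices, `[[`, character(1), "tissue_name")
  if (anyDuplicated(tissues)) stop("duplicate tissue: ",
                                   tissues[duplicated(tissues)][1])
  # placement is label-driven: tissue axis order must not depend on the
  # order the matrices were supplied in
  tissues <- sort(tissues, method = "radix")
  treatments <- sample_map$treatments
  reps <- seq_len(sample_map$n_replicates)
  vals <- array(NA_real_,
                dim = c(length(genes), length(tissues), length(treatments),
                        length(reps)),
                dimnames = list(genes, tissues, treatments,
                                paste0("rep", reps)))
  for (m in matrices) {
    j <- match(m$tissue_name, tissues)
    for (s in seq_len(ncol(m$counts))) {
      k <- match(m$sample_labels$treatment[s], treatments)
      r <- match(m$sample_labels$replicate[s], reps)
      if (is.na(k) || is.na(r))
        stop(sprintf("sample (%s, %s) of tissue %s is outside the sample map",
                     m$sample_labels$treatment[s],
                     m$sample_labels$replicate[s], m$tissue_name))
      if (!is.na(vals[1, j, k, r]))
        stop(sprintf("duplicate cell (%s, %s, rep %d)", m$tissue_name,
                     treatments[k], reps[r]))
      vals[, j, k, r] <- m$counts[, s]
    }
  }
  miss <- which(is.na(vals[1, , , , drop = FALSE]), arr.ind = TRUE)
  if (nrow(miss) > 0)
    stop(sprintf("missing cell (%s, %s, rep %s)%s", tissues[miss[1, 2]],
                 treatments[miss[1, 3]], miss[1, 4],
                 if (nrow(miss) > 1) sprintf(" and %d more", nrow(miss) - 1) else ""))
  structure(list(values = vals, standardized = FALSE, log_transform = NA),
            class = "expression_tensor")
}

#' Standardize each sample fiber of an expression tensor
#'
#' Optionally log-transforms counts as `log2(x + pseudocount)`, then centers
#' and scales every gene fiber (fixed tissue j, treatment k, replicate m) so
#' that \eqn{\sum_i x_{ijkm} = 0} and \eqn{\sum_i x_{ijkm}^2 = N}.  The
#' scale uses the population (1/N) variance so the sum-of-squares constraint
#' holds exactly.  All samples become directly comparable before
#' decomposition; no between-sample normalization is applied.
#'
#' @param tensor an unstandardized `expression_tensor`.
#' @param log_transform logical; log2-transform counts first (default TRUE —
#'   raw RNA-seq counts are heavy-tailed and the chi-squared machinery
#'   downstream assumes roughly Gaussian loadings).
#' @param pseudocount positive offset added before the log (default 1).
#' @return the standardized `expression_tensor`.
#' @export
standardize_tensor <- function(tensor, log_transform = TRUE, pseudocount = 1) {
  stopifnot(inherits(tensor, "expression_tensor"))
  if (isTRUE(tensor$standardized)) stop("tensor is already standardized")
  v <- tensor$values
  N <- dim(v)[1]
  if (N < 2) stop("need at least 2 genes to standardize")
  if (log_transform) {
    stopifnot(pseudocount > 0)
    v <- log2(v + pseudocount)
  }
  d <- dim(v)
  mat <- matrix(v, nrow = N)                 # fibers over genes as columns
  mu <- colMeans(mat)
  mat <- sweep(mat, 2, mu)
  ssq <- colMeans(mat ^ 2)                   # population variance
  if (any(ssq <= 0)) {
    bad <- which(ssq <= 0)[1]
    idx <- arrayInd(bad, d[-1])
    stop(sprintf(
      "zero-variance sample fiber at (tissue %s, treatment %s, replicate %s): scaling undefined",
      dimnames(v)[[2]][idx[1]], dimnames(v)[[3]][idx[2]],
      dimnames(v)[[4]][idx[3]]))
  }
  mat <- sweep(mat, 2, sqrt(ssq), "/")       # now sum of squares = N
  out <- array(mat, dim = d, dimnames = dimnames(v))
  structure(list(values = out, standardized = TRUE,
                 log_transform = log_transform,
                 pseudocount = if (log_transform) pseudocount else NA),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_tensor: %d genes x %d tissues x %d treatments x %d replicates (%s)\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$standardized)) "standardized" else "raw counts"))
  invisible(x)
}
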