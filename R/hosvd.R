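# Mode-n matricization and multiplication, array axis order
# (gene, tissue, treatment, replicate).

unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

fold <- function(mat, mode, target_dim) {
  perm <- c(mode, setdiff(seq_along(target_dim), mode))
  arr <- array(mat, dim = target_dim[perm])
  aperm(arr, order(perm))
}

# x times matrix `mat` along `mode` (mat: new_dim x old_dim)
ttm <- function(x, mat, mode) {
  d <- dim(x)
  res <- mat %*% unfold(x, mode)
  d[mode] <- nrow(mat)
  fold(res, mode, d)
}

# deterministic sign convention: largest-|.| component of each column positive
fix_signs <- function(u) {
  flip <- apply(u, 2, function(col) col[which.max(abs(col))] < 0)
  u[, flip] <- -u[, flip, drop = FALSE]
  u
}

#' Higher-order SVD of a standardized expression tensor
#'
#' Tucker-form decomposition
#' \deqn{x_{ijkm} = \sum_{\ell_1 \ell_2 \ell_3 \ell_4}
#'   G(\ell_1,\ell_2,\ell_3,\ell_4)\,
#'   u_{\ell_1 j}\, u_{\ell_2 k}\, u_{\ell_3 m}\, u_{\ell_4 i}}
#' where each factor matrix holds the left singular vectors of the
#' corresponding mode unfolding (economy form; the gene factor is N x r4
#' with r4 bounded by the product of the other dimensions, never N x N) and
#' the core tensor G is the multilinear projection of the data onto all
#' four factors.  Vectors within each mode are ordered by decreasing
#' singular value of that unfolding; each vector's sign is fixed so its
#' largest-magnitude component is positive, making runs reproducible.
#'
#' Indexing follows the convention \eqn{\ell_1} = tissue mode, \eqn{\ell_2}
#' = treatment mode, \eqn{\ell_3} = replicate mode, \eqn{\ell_4} = gene
#' mode, all 1-based ("first singular value vector" = the uniform-like one).
#'
#' @param tensor a standardized [expression_tensor] (see
#'   [standardize_tensor()]).
#' @return object of class `hosvd_result`: list with factor matrices
#'   `U_tissue`, `U_treatment`, `U_replicate`, `U_gene`, the core array
#'   `core` indexed `[l1, l2, l3, l4]`, singular values per mode `d`, and
#'   `mode_ranks`.
#' @export
hosvd <- function(tensor) {
  stopifnot(inherits(tensor, "expression_tensor"))
  if (!isTRUE(tensor$standardized))
    stop("hosvd() requires a standardized tensor")
  x <- tensor$values
  if (any(!is.finite(x))) stop("tensor contains non-finite entries")
  sv <- lapply(1:4, function(mode) {
    s <- svd(unfold(x, mode))
    list(u = fix_signs(s$u), d = s$d[seq_len(ncol(s$u))])
  })
  core <- x
  for (mode in 1:4) core <- ttm(core, t(sv[[mode]]$u), mode)
  # core index order (l1 tissue, l2 treatment, l3 replicate, l4 gene)
  core <- aperm(core, c(2, 3, 4, 1))
  structure(list(
    U_gene = sv[[1]]$u, U_tissue = sv[[2]]$u, U_treatment = sv[[3]]$u,
    U_replicate = sv[[4]]$u, core = core,
    d = list(gene = sv[[1]]$d, tissue = sv[[2]]$d, treatment = sv[[3]]$d,
             replicate = sv[[4]]$d),
    mode_ranks = dim(core),
    axis_labels = dimnames(x)), class = "hosvd_result")
}

#' @export
print.hosvd_result <- function(x, ...) {
  r <- x$mode_ranks
  cat(sprintf("hosvd_result: core %d x %d x %d x %d (tissue, treatment, replicate, gene)\n",
              r[1], r[2], r[3], r[4]))
  invisible(x)
}

#' Reconstruct the tensor from an HOSVD result
#'
#' Evaluates the Tucker sum; at full mode ranks this reproduces the input
#' tensor to numerical precision.  Works equally for truncated results
#' (factor matrices restricted to leading columns with the matching core
#' sub-array).
#'
#' @param result an `hosvd_result`.
#' @return numeric 4-way array, gene x tissue x treatment x replicate.
#' @export
reconstruct <- function(result) {
  core <- aperm(result$core, c(4, 1, 2, 3))   # back to array axis order
  U <- list(result$U_gene, result$U_tissue, result$U_treatment,
            result$U_replicate)
  for (mode in 1:4) {
    if (ncol(U[[mode]]) != dim(core)[mode])
      stop("shape mismatch between core and factor matrix in mode ", mode)
    core <- ttm(core, U[[mode]], mode)
  }
  dimnames(core) <- result$axis_labels
  core
}

#' Extract a gene-mode slice of the core tensor
#'
#' Returns \eqn{G(\ell_1, \ell_2, \ell_3, \cdot)} as a vector over the
#' gene-mode index \eqn{\ell_4}; inspecting these slices (with \eqn{\ell_3
#' = 1}, since the first replicate vector is constant across replicates) is
#' how gene-mode vectors are matched to a chosen tissue/treatment
#' dependence.
#'
#' @param result an `hosvd_result`.
#' @param l1,l2,l3 1-based mode indices (tissue, treatment, replicate).
#' @return named numeric vector (`l4=1`, `l4=2`, ...).
#' @export
core_slice <- function(result, l1, l2, l3) {
  r <- result$mode_ranks
  if (l1 < 1 || l1 > r[1] || l2 < 1 || l2 > r[2] || l3 < 1 || l3 > r[3])
    stop("core index out of range")
  v <- result$core[l1, l2, l3, ]
  names(v) <- paste0("l4=", seq_along(v))
  v
}
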