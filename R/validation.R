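#' Pooled two-group test of a gene selection across a label split
#'
#' Pools every standardized expression value x[i, j, k, m] with gene i in
#' the selection and the split-axis label in `members`, against the pool
#' with the label in `complement` (each value is one observation — no
#' per-gene averaging), and compares the two pools by a two-sided Welch
#' t-test and a two-sided Wilcoxon rank-sum test.  A selection that tracks
#' the split should show strongly shifted pools.
#'
#' @param tensor a standardized [expression_tensor].
#' @param selection a `gene_selection` with a non-empty selected set.
#' @param split a `group_split` over the tissue or treatment axis.
#' @return object of class `group_test_result`: context, axis, split,
#'   `t_p`, `wilcoxon_p`, pool sizes `n_in` / `n_out`, and the pool means.
#' @export
two_group_test <- function(tensor, selection, split) {
  stopifnot(inherits(tensor, "expression_tensor"),
            inherits(selection, "gene_selection"),
            inherits(split, "group_split"))
  if (length(selection$selected) == 0) stop("empty gene selection")
  axis <- match(split$axis, c("tissue", "treatment")) + 1L
  if (is.na(axis)) stop("split axis must be 'tissue' or 'treatment'")
  labels <- dimnames(tensor$values)[[axis]]
  gi <- match(selection$selected, dimnames(tensor$values)[[1]])
  if (anyNA(gi)) stop("selection refers to genes absent from the tensor")
  take <- function(which_labels) {
    idx <- match(which_labels, labels)
    if (axis == 2L) as.vector(tensor$values[gi, idx, , , drop = FALSE])
    else            as.vector(tensor$values[gi, , idx, , drop = FALSE])
  }
  a <- take(split$members); b <- take(split$complement)
  if (length(a) == 0 || length(b) == 0) stop("empty pool on one side of the split")
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  structure(list(context_label = selection$context_label, axis = split$axis,
                 split = split, t_p = tt$p.value, wilcoxon_p = wt$p.value,
                 n_in = length(a), n_out = length(b),
                 mean_in = mean(a), mean_out = mean(b)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s vs %s axis {%s}: t P = %.3g, Wilcoxon P = %.3g (n = %d/%d)\n",
              x$context_label, x$axis, paste(x$split$members, collapse = ", "),
              x$t_p, x$wilcoxon_p, x$n_in, x$n_out))
  invisible(x)
}

#' Overlap structure of several gene selections
#'
#' Computes the count of genes in every Venn region of the selections'
#' gene sets (each gene counted in exactly one region, identified by its
#' membership pattern) and all pairwise Jaccard indices.
#'
#' @param selections list (>= 2) of `gene_selection` objects, or plain
#'   character vectors of gene identifiers.  Names are taken from
#'   `context_label` where available.
#' @return list with `regions` (data.frame: membership pattern per
#'   selection, count) and `jaccard` (symmetric matrix).
#' @export
overlap_table <- function(selections) {
  stopifnot(length(selections) >= 2)
  sets <- lapply(selections, function(s)
    if (inherits(s, "gene_selection")) s$selected else as.character(s))
  nm <- names(selections)
  if (is.null(nm)) nm <- rep("", length(sets))
  auto <- vapply(selections, function(s)
    if (inherits(s, "gene_selection")) s$context_label else "", character(1))
  nm <- ifelse(nzchar(nm), nm, ifelse(nzchar(auto), auto,
                                      paste0("set", seq_along(sets))))
  names(sets) <- nm
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, nm))
  pattern <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts), row.names = NULL)
  for (i in seq_along(nm))
    regions[[nm[i]]] <- substr(regions$pattern, i, i) == "1"
  jac <- matrix(1, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i != j) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- if (u == 0) NA_real_ else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  list(regions = regions, jaccard = jac)
}
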