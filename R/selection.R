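#' Identify a tissue group from one tissue-mode singular vector
#'
#' Tissues whose loading magnitude reaches `dominance` times the largest
#' magnitude form the group; the rest form the complement.  A near-constant
#' vector (typically the first one) places every tissue in the group,
#' signalling "no tissue specificity" — callers should skip such vectors.
#'
#' @param result an `hosvd_result`.
#' @param l1 1-based tissue-mode vector index.
#' @param dominance fraction in (0, 1]; default 0.5.  The grouping in the
#'   underlying method is a judgement call made by eye on the loading plot,
#'   so the full loading vector is returned for manual override.
#' @return object of class `group_split`: list with `axis = "tissue"`,
#'   `members`, `complement`, `loadings`, and `provenance`.
#' @export
identify_tissue_groups <- function(result, l1, dominance = 0.5) {
  if (dominance <= 0 || dominance > 1) stop("dominance must be in (0, 1]")
  if (l1 < 1 || l1 > ncol(result$U_tissue)) stop("l1 out of range")
  u <- result$U_tissue[, l1]
  names(u) <- result$axis_labels[[2]]
  members <- names(u)[abs(u) >= dominance * max(abs(u))]
  structure(list(axis = "tissue", members = members,
                 complement = setdiff(names(u), members), loadings = u,
                 provenance = list(rule = "dominance", l1 = l1,
                                   dominance = dominance)),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("group_split (%s): {%s} vs %d other(s)\n", x$axis,
              paste(x$members, collapse = ", "), length(x$complement)))
  invisible(x)
}

#' Split treatments into two groups on the second/third singular-vector plane
#'
#' The first treatment-mode vector is uniform-like and carries no contrast;
#' the second and third spread the treatments so that drug-treated
#' conditions separate from control-like conditions along one direction
#' while drug-to-drug diversity spreads perpendicular to it.  Treatments
#' are projected onto the (u2, u3) plane and split by 2-means; Lloyd
#' iterations are started from every pair of distinct projected points and
#' the lowest within-cluster sum of squares wins, which makes the split
#' deterministic and, at this problem size (18 points), effectively exact.
#'
#' @param result an `hosvd_result` with at least 3 treatment-mode vectors.
#' @return list with `split` (a `group_split`, `members` = the smaller
#'   cluster, typically the control-like side) and `coordinates` (data.frame
#'   of treatment, u2, u3, group) for plotting or manual override.
#' @export
classify_treatment_axes <- function(result) {
  if (ncol(result$U_treatment) < 3)
    stop("need at least 3 treatment-mode singular vectors")
  coords <- result$U_treatment[, 2:3, drop = FALSE]
  rownames(coords) <- result$axis_labels[[3]]
  dd <- as.matrix(stats::dist(coords))
  if (max(dd) == 0) stop("degenerate input: all projected treatments coincide")
  n <- nrow(coords)
  best <- NULL
  for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
    if (dd[a, b] == 0) next
    km <- suppressWarnings(
      stats::kmeans(coords, centers = coords[c(a, b), , drop = FALSE]))
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
      best <- km
  }
  g1 <- rownames(coords)[best$cluster == 1]
  g2 <- rownames(coords)[best$cluster == 2]
  if (length(g2) < length(g1)) { tmp <- g1; g1 <- g2; g2 <- tmp }
  split <- structure(list(axis = "treatment", members = g1, complement = g2,
                          loadings = coords,
                          provenance = list(rule = "2-means on (u2, u3)",
                                            init = "best of all point pairs")),
                     class = "group_split")
  list(split = split,
       coordinates = data.frame(treatment = rownames(coords),
                                u2 = coords[, 1], u3 = coords[, 2],
                                group = ifelse(rownames(coords) %in% g1,
                                               "A", "B"),
                                row.names = NULL))
}

#' Rank gene-mode vectors by core-tensor weight for a chosen context
#'
#' For a fixed tissue-mode vector `l1`, treatment-mode candidates
#' `l2_candidates` (default the drug-contrast vectors 2 and 3) and
#' replicate-mode vector `l3` (default 1, the between-replicate-constant
#' one), scores every gene-mode index by
#' `max over l2 of |G(l1, l2, l3, l4)|` and returns the `top` indices by
#' decreasing score.  The first gene-mode vector mirrors the contrast-free
#' first vectors of the other modes and is excluded by default.
#'
#' @param result an `hosvd_result`.
#' @param l1 tissue-mode index.
#' @param l2_candidates treatment-mode indices to scan (default `c(2, 3)`).
#' @param l3 replicate-mode index (default 1).
#' @param top how many gene-mode indices to return.
#' @param exclude_first drop `l4 = 1` from the ranking (default TRUE).
#' @return data.frame with columns `l4` and `score`, in decreasing score.
#' @export
select_ell4 <- function(result, l1, l2_candidates = c(2, 3), l3 = 1,
                        top = 1, exclude_first = TRUE) {
  if (length(l2_candidates) == 0) stop("l2_candidates must be non-empty")
  if (top < 1) stop("top must be >= 1")
  r <- result$mode_ranks
  if (l1 > r[1] || any(l2_candidates > r[2]) || l3 > r[3])
    stop("core index out of range")
  scores <- apply(abs(result$core[l1, l2_candidates, l3, , drop = FALSE]),
                  4, max)
  l4 <- seq_len(r[4])
  if (exclude_first) { scores <- scores[-1]; l4 <- l4[-1] }
  ord <- order(scores, decreasing = TRUE)[seq_len(min(top, length(l4)))]
  data.frame(l4 = l4[ord], score = scores[ord])
}

#' Chi-squared P-values for genes from selected gene-mode loadings
#'
#' Treats each selected gene-mode singular vector as zero-mean Gaussian
#' across genes (the standardization constraint forces zero-mean fibers),
#' standardizes each loading by the vector's standard deviation
#' \eqn{\sigma_{\ell_4}} (population form about zero), sums the squares
#' across the selected vectors and refers the sum to the chi-squared
#' distribution with degrees of freedom equal to the number of vectors:
#' \deqn{P_i = P_{\chi^2}\left[> \sum_{\ell_4}
#'   \left(u_{\ell_4 i}/\sigma_{\ell_4}\right)^2\right].}
#' With one vector this is the squared-z-score tail test; with several it
#' is its standard chi-squared extension.
#'
#' @param result an `hosvd_result`.
#' @param ell4 integer vector of gene-mode indices.
#' @return named numeric vector of per-gene P-values.
#' @export
compute_gene_pvalues <- function(result, ell4) {
  if (length(ell4) == 0) stop("ell4 must be non-empty")
  if (any(ell4 < 1 | ell4 > ncol(result$U_gene))) stop("ell4 out of range")
  stat <- 0
  for (l in ell4) {
    u <- result$U_gene[, l]
    sigma <- sqrt(mean(u ^ 2))
    if (sigma == 0) stop("gene-mode vector ", l, " has zero standard deviation")
    stat <- stat + (u / sigma) ^ 2
  }
  p <- stats::pchisq(stat, df = length(ell4), lower.tail = FALSE)
  names(p) <- result$axis_labels[[1]]
  p
}

#' Benjamini-Hochberg adjustment of per-gene P-values
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), delegated to
#' [stats::p.adjust()].
#'
#' @param p numeric vector of P-values in `[0, 1]`.
#' @return adjusted P-values, same names and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NaN/NA p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select genes for one tissue-group context
#'
#' Composes [compute_gene_pvalues()], [bh_adjust()] and strict thresholding
#' (adjusted P < `threshold`) into a `gene_selection` carrying full
#' provenance: the gene-mode vectors used, their sigmas, raw and adjusted
#' P-values and the selected gene set.
#'
#' @param result an `hosvd_result`.
#' @param ell4 gene-mode vector indices to combine.
#' @param threshold adjusted-P cutoff in (0, 1); default 0.01.
#' @param context_label name for this selection context (e.g. "neuron").
#' @return object of class `gene_selection`.
#' @export
select_genes <- function(result, ell4, threshold = 0.01,
                         context_label = "context") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p <- compute_gene_pvalues(result, ell4)
  adj <- bh_adjust(p)
  sigma <- vapply(ell4, function(l) sqrt(mean(result$U_gene[, l] ^ 2)),
                  numeric(1))
  structure(list(context_label = context_label, ell4 = ell4,
                 p_values = p, adjusted_p = adj,
                 selected = names(p)[adj < threshold],
                 threshold = threshold, sigma = sigma),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection '%s': %d gene(s) at adjusted P < %g (l4 = %s)\n",
              x$context_label, length(x$selected), x$threshold,
              paste(x$ell4, collapse = ", ")))
  invisible(x)
}

#' Export a gene selection
#'
#' Writes (a) a plain one-symbol-per-line list of the selected genes, ready
#' for upload to enrichment services, and (b) a tab-separated table of
#' gene, per-vector loadings, P, adjusted P and selected flag.
#'
#' @param selection a `gene_selection`.
#' @param result the `hosvd_result` it came from (for loadings).
#' @param list_path,table_path output paths (either may be `NULL` to skip).
#' @export
export_selection <- function(selection, result, list_path = NULL,
                             table_path = NULL) {
  if (!is.null(list_path))
    writeLines(selection$selected, list_path)
  if (!is.null(table_path)) {
    tab <- data.frame(gene = names(selection$p_values))
    for (i in seq_along(selection$ell4))
      tab[[paste0("u_l4_", selection$ell4[i])]] <-
        result$U_gene[, selection$ell4[i]]
    tab$p_value <- selection$p_values
    tab$adjusted_p <- selection$adjusted_p
    tab$selected <- tab$gene %in% selection$selected
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
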