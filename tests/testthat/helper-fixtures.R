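# Small in-code fixtures shared across test files.

# random standardized tensor of the given shape
random_tensor <- function(n_genes, n_tis, n_trt, n_rep, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n_genes * n_tis * n_trt * n_rep),
               dim = c(n_genes, n_tis, n_trt, n_rep),
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               paste0("tis", seq_len(n_tis)),
                               paste0("trt", seq_len(n_trt)),
                               paste0("rep", seq_len(n_rep))))
  standardize_tensor(
    structure(list(values = arr, standardized = FALSE),
              class = "expression_tensor"),
    log_transform = FALSE)
}

# tiny count matrix builder
tiny_counts <- function(tissue = "Brain", n_genes = 3,
                        treatments = c("drugA", "ctrl"), n_rep = 2,
                        seed = 1) {
  set.seed(seed)
  labels <- data.frame(treatment = rep(treatments, each = n_rep),
                       replicate = rep(seq_len(n_rep), length(treatments)))
  count_matrix(tissue, sprintf("gene%02d", seq_len(n_genes)), labels,
               matrix(rpois(n_genes * nrow(labels), 50), n_genes))
}

# small planted-signal spec that runs in well under a second
small_spec <- function(n_genes = 400, seed = 1, ...) {
  drug_tissue_spec(n_genes = n_genes,
                   genes_per_group = as.integer(min(20, n_genes %/% 3)),
                   seed = seed, ...)
}

# full quadruple-loop core contraction: the independent oracle for hosvd()
brute_force_core <- function(x, res) {
  r <- res$mode_ranks
  G <- array(0, r)
  d <- dim(x)
  for (l1 in seq_len(r[1])) for (l2 in seq_len(r[2]))
    for (l3 in seq_len(r[3])) for (l4 in seq_len(r[4])) {
      acc <- 0
      for (j in seq_len(d[2])) for (k in seq_len(d[3]))
        for (m in seq_len(d[4]))
          acc <- acc + sum(x[, j, k, m] * res$U_gene[, l4]) *
            res$U_tissue[j, l1] * res$U_treatment[k, l2] *
            res$U_replicate[m, l3]
      G[l1, l2, l3, l4] <- acc
    }
  G
}

run_small_pipeline <- function(spec, out_dir = tempfile("run"), ...) {
  suppressMessages(run_pipeline(run_config(
    input = list(mode = "synthetic", spec = spec),
    out_dir = out_dir, seed = spec$seed, ...)))
}

# match a pipeline context to a planted group by its tissue set
context_for_group <- function(res, truth, group) {
  hits <- Filter(function(ctx)
    setequal(ctx$split$members, truth[[group]]$tissues), res$contexts)
  if (length(hits) == 0) NULL else hits[[1]]
}

precision_recall <- function(selected, planted) {
  c(precision = if (length(selected)) mean(selected %in% planted) else NA_real_,
    recall = mean(planted %in% selected))
}
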