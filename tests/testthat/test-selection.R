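# minimal hand-built hosvd_result: only the fields the selection layer reads
fake_result <- function(U_gene = NULL, U_tissue = NULL, U_treatment = NULL,
                        core = NULL, genes = NULL, tissues = NULL,
                        treatments = NULL) {
  structure(list(
    U_gene = U_gene, U_tissue = U_tissue, U_treatment = U_treatment,
    U_replicate = matrix(1), core = core,
    mode_ranks = if (!is.null(core)) dim(core) else
      c(if (!is.null(U_tissue)) ncol(U_tissue) else 1,
        if (!is.null(U_treatment)) ncol(U_treatment) else 1, 1,
        if (!is.null(U_gene)) ncol(U_gene) else 1),
    axis_labels = list(genes, tissues, treatments, "rep1")),
    class = "hosvd_result")
}

test_that("tissue grouping by dominance handles dominant, constant and bad input", {
  U <- cbind(rep(0.5, 4), c(0.9, 0.05, -0.1, 0.08))
  res <- fake_result(U_tissue = U, tissues = c("A", "B", "C", "D"))
  expect_equal(identify_tissue_groups(res, 2, 0.5)$members, "A")
  all_in <- identify_tissue_groups(res, 1, 0.5)
  expect_setequal(all_in$members, c("A", "B", "C", "D"))
  expect_length(all_in$complement, 0)
  expect_error(identify_tissue_groups(res, 2, 0), "dominance")
  expect_error(identify_tissue_groups(res, 2, 1.5), "dominance")
  expect_error(identify_tissue_groups(res, 99), "out of range")
})

test_that("well-separated treatment clouds split exactly", {
  set.seed(8)
  n <- 10
  cloud <- rep(c(-1, 1), each = n / 2)
  U <- cbind(rep(1 / sqrt(n), n),
             cloud / 4 + runif(n, -0.02, 0.02),
             runif(n, -0.02, 0.02))
  res <- fake_result(U_treatment = U,
                     treatments = paste0("t", 1:n))
  out <- classify_treatment_axes(res)
  left <- paste0("t", 1:(n / 2))
  expect_true(setequal(out$split$members, left) ||
                setequal(out$split$complement, left))
  expect_equal(nrow(out$coordinates), n)
  # swapping members/complement is just labelling: they partition the axis
  expect_setequal(c(out$split$members, out$split$complement), paste0("t", 1:n))
})

test_that("select_ell4 ranks gene-mode vectors by core magnitude", {
  core <- array(0, c(2, 3, 1, 5))
  core[2, 2, 1, ] <- c(50, 3, -20, 1, 0.5)   # l4 = 1 big but excluded
  core[2, 3, 1, ] <- c(0, 8, 2, -30, 0)
  res <- fake_result(core = core)
  top <- select_ell4(res, l1 = 2, l2_candidates = c(2, 3), l3 = 1, top = 3)
  expect_equal(top$l4, c(4, 3, 2))
  expect_equal(top$score, c(30, 20, 8))
  expect_equal(select_ell4(res, 2, c(2, 3), 1, top = 1,
                           exclude_first = FALSE)$l4, 1)
  expect_error(select_ell4(res, 2, integer(), 1), "non-empty")
  expect_error(select_ell4(res, 9, c(2, 3), 1), "out of range")
})

test_that("chi-squared P-values match their closed forms", {
  u <- c(2, 0.5, -0.5, 0.5, -0.5)       # population rms exactly 1
  res <- fake_result(U_gene = cbind(u), genes = paste0("g", 1:5))
  p <- compute_gene_pvalues(res, 1)
  expect_equal(unname(p["g1"]), 0.0455, tolerance = 1e-4)
  # independent closed form: chi2(1) upper tail at z^2 is 2 * (1 - Phi(|z|))
  expect_equal(unname(p), 2 * (1 - pnorm(abs(u))), tolerance = 1e-12)
  # a zero loading gives P = 1
  u0 <- c(0, 1, -1, 1, -1)
  res0 <- fake_result(U_gene = cbind(u0), genes = paste0("g", 1:5))
  expect_equal(unname(compute_gene_pvalues(res0, 1)["g1"]), 1)
  expect_error(compute_gene_pvalues(res0, integer()), "non-empty")
  expect_error(compute_gene_pvalues(
    fake_result(U_gene = cbind(rep(0, 5)), genes = paste0("g", 1:5)), 1),
    "zero standard deviation")
})

test_that("null Gaussian loadings give uniform P-values", {
  set.seed(31)
  res <- fake_result(U_gene = cbind(rnorm(2000)),
                     genes = sprintf("g%04d", 1:2000))
  p <- compute_gene_pvalues(res, 1)
  expect_lt(suppressWarnings(
    ks.test(p, "punif")$statistic), 0.05)
})

test_that("the multi-vector statistic is the sum of single-vector statistics", {
  set.seed(32)
  U <- cbind(rnorm(500), rnorm(500))
  res <- fake_result(U_gene = U, genes = sprintf("g%03d", 1:500))
  s1 <- qchisq(compute_gene_pvalues(res, 1), 1, lower.tail = FALSE)
  s2 <- qchisq(compute_gene_pvalues(res, 2), 1, lower.tail = FALSE)
  s12 <- qchisq(compute_gene_pvalues(res, c(1, 2)), 2, lower.tail = FALSE)
  expect_equal(s12, s1 + s2, tolerance = 1e-8)
})

test_that("bh_adjust reproduces the step-up worked example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(33)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p rank
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "lie in")
})

test_that("select_genes composes the pieces with strict thresholding", {
  set.seed(34)
  u <- c(rnorm(20, 0, 8), rnorm(480))   # 20 loud genes
  res <- fake_result(U_gene = cbind(u / sqrt(mean(u ^ 2))),
                     genes = sprintf("g%03d", 1:500))
  sel <- select_genes(res, 1, threshold = 0.01, context_label = "loud")
  expect_s3_class(sel, "gene_selection")
  expect_true(all(sel$adjusted_p >= sel$p_values - 1e-15))
  expect_identical(sel$selected,
                   names(sel$p_values)[sel$adjusted_p < 0.01])
  expect_gte(length(sel$selected), 5)
  expect_lt(mean(!grepl("^g0[01]", sel$selected)), 0.2)
  # an impossibly small threshold empties the selection; zero is rejected
  expect_length(select_genes(res, 1, threshold = 1e-300)$selected, 0)
  expect_error(select_genes(res, 1, threshold = 0), "threshold")
})

test_that("selection labels are invariant to gene-order permutation", {
  spec <- small_spec(n_genes = 300, seed = 12)
  sm <- sample_map(spec$treatment_names, spec$controls)
  tens <- standardize_tensor(assemble_tensor(generate_dataset(spec)$matrices,
                                             sm))
  set.seed(1)
  perm <- sample(300)
  permuted <- tens
  permuted$values <- tens$values[perm, , , , drop = FALSE]
  pick <- function(t) {
    dec <- hosvd(t)
    gs <- identify_tissue_groups(dec, 2, 0.5)
    sel <- select_genes(dec, select_ell4(dec, 2)$l4[1])
    sort(sel$selected)
  }
  expect_identical(pick(tens), pick(permuted))
})

test_that("under the global null the selected fraction stays near the FDR level", {
  fractions <- vapply(1:20, function(s) {
    tens <- random_tensor(500, 6, 5, 2, seed = 100 + s)
    dec <- hosvd(tens)
    length(select_genes(dec, 2, threshold = 0.01)$selected) / 500
  }, numeric(1))
  expect_lte(mean(fractions), 0.01 + 3 * sqrt(0.01 / 500))
})
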