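fake_selection <- function(genes, label = "ctx") {
  structure(list(context_label = label, ell4 = 2L,
                 p_values = setNames(rep(0.001, length(genes)), genes),
                 adjusted_p = setNames(rep(0.005, length(genes)), genes),
                 selected = genes, threshold = 0.01, sigma = 1),
            class = "gene_selection")
}

fake_split <- function(axis, members, all_labels) {
  structure(list(axis = axis, members = members,
                 complement = setdiff(all_labels, members),
                 loadings = NULL, provenance = list(rule = "manual")),
            class = "group_split")
}

test_that("pooled tests are symmetric under swapping the two sides", {
  tens <- random_tensor(30, 6, 4, 2, seed = 41)
  sel <- fake_selection(sprintf("g%03d", 1:10))
  tis <- dimnames(tens$values)[[2]]
  s1 <- fake_split("tissue", tis[1:2], tis)
  s2 <- fake_split("tissue", tis[3:6], tis)
  r1 <- two_group_test(tens, sel, s1)
  r2 <- two_group_test(tens, sel, s2)
  expect_equal(r1$t_p, r2$t_p, tolerance = 1e-12)
  expect_equal(r1$wilcoxon_p, r2$wilcoxon_p, tolerance = 1e-12)
  expect_equal(r1$n_in, r2$n_out)
  # pool sizes: 10 genes x tissues x 4 treatments x 2 replicates
  expect_equal(r1$n_in, 10 * 2 * 4 * 2)
})

test_that("pooled t-test P-values are uniform under the null", {
  pvals <- vapply(1:200, function(s) {
    tens <- random_tensor(12, 6, 3, 2, seed = 500 + s)
    sel <- fake_selection(sprintf("g%03d", 1:4))
    tis <- dimnames(tens$values)[[2]]
    two_group_test(tens, sel, fake_split("tissue", tis[1:3], tis))$t_p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(pvals, "punif")$statistic), 0.1)
})

test_that("treatment-axis pooling works and empty inputs error", {
  tens <- random_tensor(20, 4, 5, 2, seed = 42)
  sel <- fake_selection(sprintf("g%03d", 1:5))
  trt <- dimnames(tens$values)[[3]]
  r <- two_group_test(tens, sel, fake_split("treatment", trt[1:2], trt))
  expect_equal(r$n_in, 5 * 4 * 2 * 2)
  expect_true(r$t_p >= 0 && r$t_p <= 1)
  expect_error(two_group_test(tens, fake_selection(character()),
                              fake_split("tissue", "tis1",
                                         dimnames(tens$values)[[2]])),
               "empty")
})

test_that("overlap_table handles identical and disjoint sets", {
  a <- fake_selection(paste0("g", 1:5), "A")
  b <- fake_selection(paste0("g", 1:5), "B")
  ov <- overlap_table(list(a, b))
  expect_equal(ov$jaccard["A", "B"], 1)
  expect_equal(ov$regions$count[ov$regions$pattern == "11"], 5L)
  expect_false(any(ov$regions$pattern %in% c("10", "01")))
  d <- fake_selection(paste0("h", 1:3), "D")
  ov2 <- overlap_table(list(a, d))
  expect_equal(ov2$jaccard["A", "D"], 0)
  expect_setequal(ov2$regions$pattern, c("10", "01"))
})

test_that("Venn regions match brute-force membership enumeration", {
  set.seed(43)
  genes <- sprintf("g%03d", 1:100)
  sets <- lapply(1:4, function(i) sample(genes, sample(10:40, 1)))
  names(sets) <- c("w", "x", "y", "z")
  ov <- overlap_table(sets)
  expect_equal(sum(ov$regions$count), length(unique(unlist(sets))))
  # brute force: classify every gene by its membership pattern
  expected <- table(vapply(unique(unlist(sets)), function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1)))
  got <- setNames(ov$regions$count, ov$regions$pattern)
  expect_equal(got[order(names(got))],
               unlist(as.list(expected))[order(names(expected))],
               ignore_attr = TRUE)
  # pairwise jaccard against direct computation
  expect_equal(ov$jaccard["w", "y"],
               length(intersect(sets$w, sets$y)) /
                 length(union(sets$w, sets$y)))
})

test_that("same-tissue-pair selections overlap while cross-group ones do not", {
  spec <- drug_tissue_spec(seed = 3)
  ds <- generate_dataset(spec)
  sm <- sample_map(spec$treatment_names, spec$controls)
  dec <- hosvd(standardize_tensor(assemble_tensor(ds$matrices, sm)))
  find_l1 <- function(tset) {
    for (l1 in 2:6)
      if (setequal(identify_tissue_groups(dec, l1, 0.5)$members, tset))
        return(l1)
    NA
  }
  l1_gas <- find_l1(spec$tissue_groups$gastro$tissues)
  l1_neu <- find_l1(spec$tissue_groups$neuron$tissues)
  expect_false(is.na(l1_gas) || is.na(l1_neu))
  ranked <- select_ell4(dec, l1_gas, top = 2)
  gas1 <- select_genes(dec, ranked$l4[1], context_label = "Gas1")
  gas2 <- select_genes(dec, ranked$l4[1:2], context_label = "Gas2")
  neuron <- select_genes(dec, select_ell4(dec, l1_neu)$l4[1],
                         context_label = "Neuron")
  ov <- overlap_table(list(gas1, gas2, neuron))
  expect_gte(ov$jaccard["Gas1", "Gas2"], 0.5)
  expect_lte(ov$jaccard["Gas1", "Neuron"], 0.1)
  expect_lte(ov$jaccard["Gas2", "Neuron"], 0.1)
})
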