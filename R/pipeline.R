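#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object.  Input is either a directory of per-tissue count tables plus a
#' [sample_map], or a [synthetic_spec] to generate from.
#'
#' @param input for count files: `list(mode = "counts", dir = <path>,
#'   sample_map = <sample_map>)`; for simulation: `list(mode = "synthetic",
#'   spec = <synthetic_spec>)`.
#' @param out_dir output directory (created if missing).
#' @param log_transform,pseudocount passed to [standardize_tensor()].
#' @param contexts `"auto"` to scan tissue-mode vectors 2..`max_scan` for
#'   tissue-specific groups, or an integer vector of tissue-mode indices.
#' @param max_scan upper tissue-mode index for auto-scan (default 8).
#' @param include_singletons keep contexts whose tissue group is a single
#'   tissue (default FALSE: they are reported but skipped, as single-tissue
#'   vectors describe one organ rather than a tissue group).
#' @param l2_candidates treatment-mode vectors scanned in the core (default
#'   `c(2, 3)`, the drug-contrast pair).
#' @param l3 replicate-mode vector (default 1, constant across replicates).
#' @param max_vectors most gene-mode vectors combined per context (default 2).
#' @param vector_ratio a second (third, ...) gene-mode vector is combined
#'   only when its core score reaches this fraction of the best one
#'   (default 0.75).
#' @param threshold adjusted-P selection cutoff (default 0.01).
#' @param dominance tissue-group dominance fraction (default 0.5).
#' @param seed integer seed recorded in the manifest (the generator also
#'   carries its own seed inside `spec`).
#' @return object of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       log_transform = TRUE, pseudocount = 1,
                       contexts = "auto", max_scan = 8L,
                       include_singletons = FALSE,
                       l2_candidates = c(2, 3), l3 = 1,
                       max_vectors = 2L, vector_ratio = 0.75,
                       threshold = 0.01, dominance = 0.5, seed = 1L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (dominance <= 0 || dominance > 1) stop("dominance must be in (0, 1]")
  stopifnot(input$mode %in% c("counts", "synthetic"))
  if (input$mode == "synthetic") stopifnot(inherits(input$spec, "synthetic_spec"))
  if (input$mode == "counts") stopifnot(inherits(input$sample_map, "sample_map"))
  structure(list(input = input, out_dir = out_dir,
                 log_transform = log_transform, pseudocount = pseudocount,
                 contexts = contexts, max_scan = as.integer(max_scan),
                 include_singletons = include_singletons,
                 l2_candidates = l2_candidates, l3 = l3,
                 max_vectors = as.integer(max_vectors),
                 vector_ratio = vector_ratio,
                 threshold = threshold, dominance = dominance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `input` takes
#' either `{mode: counts, dir: ..., controls: [...], treatments: [...]}`
#' (a default [sample_map] is built from `treatments`/`controls`) or
#' `{mode: synthetic, spec: <path to a synthetic-spec YAML>}`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  input <- if (identical(cfg$input$mode, "synthetic")) {
    spec <- if (!is.null(cfg$input$spec)) read_synthetic_spec(cfg$input$spec)
            else drug_tissue_spec()
    list(mode = "synthetic", spec = spec)
  } else {
    treatments <- if (!is.null(cfg$input$treatments))
      as.character(cfg$input$treatments) else study_treatments()
    list(mode = "counts", dir = cfg$input$dir,
         sample_map = sample_map(treatments,
                                 controls = as.character(cfg$input$controls),
                                 n_replicates = cfg$input$n_replicates %||% 2L))
  }
  args <- cfg[setdiff(names(cfg), "input")]
  do.call(run_config, c(list(input = input), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full tensor-decomposition feature-extraction pipeline
#'
#' Executes read/generate, gene harmonization, tensor assembly, per-sample
#' standardization, HOSVD, treatment-axis classification, and — per
#' tissue-group context — tissue grouping, core-guided gene-mode vector
#' selection, chi-squared/BH gene selection, and pooled two-group
#' validation tests on both axes; finally the overlap table across
#' contexts.  All numerical tables, per-context gene lists and a JSON run
#' manifest sufficient to reproduce the run are written under
#' `config$out_dir`.
#'
#' @param config a [run_config].
#' @return (invisibly) list with the tensor, `hosvd_result`, treatment
#'   split, per-context results, overlap table and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    if (config$input$mode == "synthetic") {
      ds <- generate_dataset(config$input$spec)
      matrices <- ds$matrices
      smap <- sample_map(config$input$spec$treatment_names,
                         controls = config$input$spec$controls,
                         n_replicates = config$input$spec$n_replicates)
      write_ground_truth(ds$truth, file.path(config$out_dir,
                                             "ground_truth.tsv"))
    } else {
      files <- list.files(config$input$dir, "_count_.*\\.txt(\\.gz)?$",
                          full.names = TRUE)
      if (length(files) == 0) stop("no count files in ", config$input$dir)
      smap <- config$input$sample_map
      matrices <- lapply(files, read_tissue_counts, sample_map = smap)
    }
    stage <- "harmonize"
    matrices <- harmonize_genes(matrices)
    stage <- "assemble"
    tensor <- assemble_tensor(matrices, smap)
    stage <- "standardize"
    tensor <- standardize_tensor(tensor, config$log_transform,
                                 config$pseudocount)
    stage <- "hosvd"
    dec <- hosvd(tensor)
    stage <- "treatment axes"
    treat <- classify_treatment_axes(dec)
    utils::write.table(treat$coordinates,
                       file.path(config$out_dir, "treatment_axes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage <- "contexts"
    l1s <- if (identical(config$contexts, "auto"))
      seq(2L, min(config$max_scan, ncol(dec$U_tissue))) else
        as.integer(config$contexts)
    contexts <- list(); skipped <- list()
    for (l1 in l1s) {
      split <- identify_tissue_groups(dec, l1, config$dominance)
      if (length(split$complement) == 0) {    # constant-like vector
        skipped[[as.character(l1)]] <- "no tissue specificity"
        next
      }
      if (length(split$members) == 1 && !config$include_singletons) {
        skipped[[as.character(l1)]] <-
          sprintf("singleton group (%s); set include_singletons to keep",
                  split$members)
        next
      }
      ranked <- select_ell4(dec, l1, config$l2_candidates, config$l3,
                            top = config$max_vectors)
      keep <- ranked$score >= config$vector_ratio * ranked$score[1]
      ell4 <- ranked$l4[keep]
      label <- sprintf("l1_%d_%s", l1, paste(split$members, collapse = "."))
      sel <- select_genes(dec, ell4, config$threshold, label)
      tests <- list(
        tissue = if (length(sel$selected))
          two_group_test(tensor, sel, split) else NULL,
        treatment = if (length(sel$selected))
          two_group_test(tensor, sel, treat$split) else NULL)
      export_selection(sel, dec,
                       list_path = file.path(config$out_dir,
                                             paste0("genes_", label, ".txt")),
                       table_path = file.path(config$out_dir,
                                              paste0("table_", label, ".tsv")))
      contexts[[label]] <- list(l1 = l1, split = split, ranked = ranked,
                                selection = sel, tests = tests)
    }
    stage <- "core report"
    write_core_report(dec, vapply(contexts, `[[`, integer(1), "l1"),
                      config$l2_candidates, config$l3,
                      file.path(config$out_dir, "core_slices.tsv"))
    stage <- "summary tables"
    write_test_table(contexts, file.path(config$out_dir, "group_tests.tsv"))
    overlaps <- if (length(contexts) >= 2)
      overlap_table(lapply(contexts, `[[`, "selection")) else NULL
    if (!is.null(overlaps)) {
      utils::write.table(overlaps$regions,
                         file.path(config$out_dir, "venn_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(overlaps$jaccard,
                         file.path(config$out_dir, "jaccard.tsv"),
                         sep = "\t", quote = FALSE)
    }
    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("tdfe")),
      seed = config$seed,
      input_mode = config$input$mode,
      synthetic_seed = if (config$input$mode == "synthetic")
        config$input$spec$seed else NULL,
      log_transform = config$log_transform,
      pseudocount = config$pseudocount,
      l2_candidates = config$l2_candidates, l3 = config$l3,
      max_vectors = config$max_vectors, vector_ratio = config$vector_ratio,
      threshold = config$threshold, dominance = config$dominance,
      tensor_shape = dim(tensor$values),
      contexts = lapply(contexts, function(ctx) list(
        l1 = ctx$l1, tissues = ctx$split$members, ell4 = ctx$selection$ell4,
        n_selected = length(ctx$selection$selected))),
      skipped = skipped)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(tensor = tensor, hosvd = dec, treatment = treat,
         contexts = contexts, skipped = skipped, overlaps = overlaps,
         manifest = manifest)
  }, error = function(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  invisible(res)
}

# core-slice report: G(l1, l2, l3, l4) for l4 = 1..10 per context
write_core_report <- function(dec, l1s, l2_candidates, l3, path) {
  rows <- list()
  n4 <- min(10, dec$mode_ranks[4])
  for (l1 in unique(l1s)) for (l2 in l2_candidates) {
    g <- core_slice(dec, l1, l2, l3)[seq_len(n4)]
    rows[[length(rows) + 1]] <-
      data.frame(l1 = l1, l2 = l2, l3 = l3, l4 = seq_len(n4), G = unname(g))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(l1 = integer(), l2 = integer(), l3 = integer(),
               l4 = integer(), G = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

write_test_table <- function(contexts, path) {
  rows <- lapply(contexts, function(ctx) data.frame(
    context = ctx$selection$context_label, l1 = ctx$l1,
    tissues = paste(ctx$split$members, collapse = ","),
    n_genes = length(ctx$selection$selected),
    tissue_t_p = if (!is.null(ctx$tests$tissue)) ctx$tests$tissue$t_p else NA,
    tissue_wilcoxon_p = if (!is.null(ctx$tests$tissue))
      ctx$tests$tissue$wilcoxon_p else NA,
    treatment_t_p = if (!is.null(ctx$tests$treatment))
      ctx$tests$treatment$t_p else NA,
    treatment_wilcoxon_p = if (!is.null(ctx$tests$treatment))
      ctx$tests$treatment$wilcoxon_p else NA))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(context = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
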