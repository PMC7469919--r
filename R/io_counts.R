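#' Sample map: canonical treatment x replicate layout of one study
#'
#' A `sample_map` declares the treatments, the designated control subset,
#' the replicate count, and how raw column headers of a count table are
#' resolved to (treatment, replicate) pairs.  The default resolver parses
#' headers of the form `"<treatment>_<replicate>"`; supply `resolver` to
#' override it for other header dialects (e.g. raw GEO column names).
#'
#' @param treatments character vector of treatment names (order is canonical).
#' @param controls character vector, subset of `treatments`, the control-like
#'   conditions (vehicle, untreated, sham).
#' @param n_replicates integer, replicates per treatment.
#' @param resolver function(header) -> list(treatment=, replicate=) or `NULL`
#'   when the header is unresolvable.  Default parses `"<treatment>_<rep>"`,
#'   splitting on the final underscore.
#' @return an object of class `sample_map`.
#' @examples
#' sm <- sample_map(c("drugA", "ctrl"), controls = "ctrl")
#' sm$resolver("drugA_2")
#' @export
sample_map <- function(treatments, controls = character(),
                       n_replicates = 2L, resolver = NULL) {
  stopifnot(is.character(treatments), length(treatments) >= 1,
            !anyDuplicated(treatments), n_replicates >= 1)
  if (!all(controls %in% treatments))
    stop("controls must be a subset of treatments")
  if (is.null(resolver)) {
    known <- treatments
    resolver <- function(header) {
      m <- regmatches(header, regexec("^(.*)_([0-9]+)$", header))[[1]]
      if (length(m) != 3 || !(m[2] %in% known)) return(NULL)
      list(treatment = m[2], replicate = as.integer(m[3]))
    }
  }
  structure(list(treatments = treatments, controls = controls,
                 n_replicates = as.integer(n_replicates),
                 resolver = resolver),
            class = "sample_map")
}

#' Count matrix for one tissue
#'
#' Genes x samples raw counts with sample labels as (treatment, replicate)
#' pairs.  Duplicate gene symbols are collapsed to the row with the largest
#' total count (a message reports how many rows were dropped).
#'
#' @param tissue_name single character label.
#' @param gene_ids character vector of gene symbols (rows of `counts`).
#' @param sample_labels data.frame with columns `treatment` (character) and
#'   `replicate` (integer), one row per column of `counts`.
#' @param counts non-negative numeric matrix, `length(gene_ids)` x
#'   `nrow(sample_labels)`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(tissue_name, gene_ids, sample_labels, counts) {
  counts <- as.matrix(counts)
  stopifnot(is.character(gene_ids),
            nrow(counts) == length(gene_ids),
            ncol(counts) == nrow(sample_labels),
            all(c("treatment", "replicate") %in% names(sample_labels)))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  key <- paste(sample_labels$treatment, sample_labels$replicate)
  if (anyDuplicated(key))
    stop("sample_labels contain a (treatment, replicate) pair more than once")
  if (anyDuplicated(gene_ids)) {
    tot <- rowSums(counts)
    keep <- !logical(length(gene_ids))
    for (g in unique(gene_ids[duplicated(gene_ids)])) {
      idx <- which(gene_ids == g)
      keep[idx] <- FALSE
      keep[idx[which.max(tot[idx])]] <- TRUE
    }
    message(sprintf("count_matrix(%s): collapsed %d duplicate gene row(s)",
                    tissue_name, sum(!keep)))
    gene_ids <- gene_ids[keep]
    counts <- counts[keep, , drop = FALSE]
  }
  rownames(counts) <- gene_ids
  structure(list(tissue_name = tissue_name, gene_ids = gene_ids,
                 sample_labels = sample_labels[, c("treatment", "replicate")],
                 counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %s  (%d genes x %d samples)\n",
              x$tissue_name, length(x$gene_ids), ncol(x$counts)))
  invisible(x)
}

#' Read a per-tissue count table
#'
#' Reads a tab-separated table (first column gene identifiers, remaining
#' columns numeric counts; gzip transparently supported), resolves each
#' column header through `sample_map$resolver`, and returns the counts with
#' columns reordered to the canonical (treatment, replicate) order of the
#' map.  Columns the resolver cannot place are reported and dropped.
#'
#' @param path file path (`.txt` or `.txt.gz`).
#' @param sample_map a [sample_map].
#' @param tissue_name label for the resulting matrix; default is parsed from
#'   the file name pattern `<prefix>_count_<Tissue>.txt[.gz]`, else the
#'   basename.
#' @return a [count_matrix].
#' @export
read_tissue_counts <- function(path, sample_map, tissue_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(tissue_name)) {
    m <- regmatches(basename(path),
                    regexec("_count_(.+?)\\.txt(\\.gz)?$", basename(path)))[[1]]
    tissue_name <- if (length(m) >= 2) m[2] else basename(path)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("format error: no count columns in ", path)
  gene_ids <- as.character(tab[[1]])
  raw <- tab[, -1, drop = FALSE]
  for (cn in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v) && !anyNA(raw[[cn]])) {
      bad <- which(is.na(v))[1]
      stop(sprintf("parse error: non-numeric count at row %d, column '%s'",
                   bad, cn))
    }
    raw[[cn]] <- v
  }
  resolved <- lapply(names(raw), sample_map$resolver)
  ok <- !vapply(resolved, is.null, logical(1))
  if (any(!ok))
    message(sprintf("read_tissue_counts(%s): dropped %d unresolvable column(s): %s",
                    tissue_name, sum(!ok),
                    paste(names(raw)[!ok], collapse = ", ")))
  if (!any(ok)) stop("format error: zero resolvable columns in ", path)
  res <- do.call(rbind, lapply(resolved[ok], function(r)
    data.frame(treatment = r$treatment, replicate = r$replicate)))
  # canonical order: treatments in map order, replicates ascending
  ord <- order(match(res$treatment, sample_map$treatments), res$replicate)
  counts <- as.matrix(raw[, ok, drop = FALSE])[, ord, drop = FALSE]
  count_matrix(tissue_name, gene_ids, res[ord, , drop = FALSE], counts)
}

#' Write a per-tissue count table
#'
#' Inverse of [read_tissue_counts()]: emits a tab-separated table whose
#' header encodes (treatment, replicate) as `"<treatment>_<replicate>"`,
#' gzip-compressed when `path` ends in `.gz`.
#'
#' @param matrix a [count_matrix].
#' @param path output path.
#' @export
write_tissue_counts <- function(matrix, path) {
  stopifnot(inherits(matrix, "count_matrix"))
  hdr <- paste(matrix$sample_labels$treatment,
               matrix$sample_labels$replicate, sep = "_")
  tab <- data.frame(gene = matrix$gene_ids, check.names = FALSE)
  tab[hdr] <- as.data.frame(matrix$counts)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Restrict a list of count matrices to their shared genes
#'
#' Tensor assembly needs one gene axis shared by every tissue.  Matrices are
#' restricted to the intersection of their gene lists, all in the canonical
#' order of the first matrix; the number of genes dropped per tissue is
#' reported.
#'
#' @param matrices list of [count_matrix] objects.
#' @return list of `count_matrix`, all with identical `gene_ids`.
#' @export
harmonize_genes <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "count_matrix")))
  shared <- Reduce(intersect, lapply(matrices, `[[`, "gene_ids"))
  if (length(shared) == 0) stop("empty gene intersection across tissues")
  shared <- matrices[[1]]$gene_ids[matrices[[1]]$gene_ids %in% shared]
  lapply(matrices, function(m) {
    dropped <- length(m$gene_ids) - length(shared)
    if (dropped > 0)
      message(sprintf("harmonize_genes: %s: dropped %d gene(s)",
                      m$tissue_name, dropped))
    count_matrix(m$tissue_name, shared, m$sample_labels,
                 m$counts[shared, , drop = FALSE])
  })
}
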