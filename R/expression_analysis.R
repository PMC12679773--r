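#' Transcript-by-sample counts matrix with tissue labels
#'
#' Container for a matrix of unique read counts (reads assigned
#' unambiguously to a single transcript by the upstream quantifier), with a
#' sample-to-tissue map and an optional transcript-to-gene map taken from
#' the newer annotation release. Counts are accepted at face value; no
#' quantification is performed here.
#'
#' @param counts numeric matrix, rows = transcripts, columns = samples, with
#'   both dimnames set; entries must be non-negative.
#' @param tissue_of named character vector mapping every sample identifier
#'   to a tissue label.
#' @param gene_of optional named character vector mapping transcript
#'   identifiers to gene identifiers.
#' @return An object of class `counts_matrix`.
#' @export
counts_matrix <- function(counts, tissue_of, gene_of = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate transcript identifiers in counts rows")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in counts columns")
  if (any(counts < 0)) stop("negative counts are not allowed")
  missing_t <- setdiff(colnames(counts), names(tissue_of))
  if (length(missing_t))
    stop("sample(s) without a tissue label: ",
         paste(utils::head(missing_t, 5L), collapse = ", "))
  tissue_of <- tissue_of[colnames(counts)]
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  if (!is.null(gene_of)) {
    missing_g <- setdiff(rownames(counts), names(gene_of))
    if (length(missing_g))
      stop("transcript(s) without a gene mapping: ",
           paste(utils::head(missing_g, 5L), collapse = ", "))
    gene_of <- gene_of[rownames(counts)]
  }
  structure(list(counts = counts, tissue_of = tissue_of, gene_of = gene_of,
                 library_sizes = lib),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat("<counts_matrix> ", nrow(x$counts), " transcripts x ", ncol(x$counts),
      " samples, ", length(unique(x$tissue_of)), " tissues\n", sep = "")
  invisible(x)
}

#' Read a counts matrix from TSV or MatrixMarket triplet files
#'
#' The TSV layout has transcript identifiers in the first column and one
#' column per sample. The MTX layout is a MatrixMarket file plus sidecar
#' one-identifier-per-line row (transcript) and column (sample) files.
#'
#' @param path counts TSV, or MTX file when `mtx_rows`/`mtx_cols` are given.
#' @param tissue_map path to a two-column TSV (`sample_id`, `tissue`).
#' @param mtx_rows,mtx_cols sidecar identifier files for the MTX layout.
#' @param gene_of optional named character vector (see [counts_matrix()]).
#' @return a [counts_matrix()].
#' @export
read_counts_matrix <- function(path, tissue_map, mtx_rows = NULL,
                               mtx_cols = NULL, gene_of = NULL) {
  if (!is.null(mtx_rows) || !is.null(mtx_cols)) {
    if (is.null(mtx_rows) || is.null(mtx_cols))
      stop("MTX input needs both mtx_rows and mtx_cols sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(mtx_rows)
    colnames(m) <- readLines(mtx_cols)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
  }
  tm <- utils::read.delim(tissue_map, header = TRUE, stringsAsFactors = FALSE)
  tissue_of <- stats::setNames(as.character(tm[[2L]]), as.character(tm[[1L]]))
  counts_matrix(m, tissue_of, gene_of = gene_of)
}

#' Read a one-identifier-per-line gene list
#'
#' @param path text file, one identifier per line; blank lines and `#`
#'   comments are ignored.
#' @return character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Counts-per-million normalization
#'
#' Each entry is divided by its sample's library size (column sum of unique
#' counts) and scaled by 1e6, so every column of the result sums to exactly
#' one million. Library sizes are per-sample; they are never pooled across
#' a tissue.
#'
#' @param x a [counts_matrix()] or a plain numeric matrix with positive
#'   column sums.
#' @return numeric matrix of CPM values, same dimnames as the input.
#' @export
cpm <- function(x) {
  m <- if (inherits(x, "counts_matrix")) x$counts else as.matrix(x)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    bad <- if (!is.null(colnames(m))) colnames(m)[lib <= 0] else which(lib <= 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(m, 2L, lib, "/") * 1e6
}

#' Transcripts new between two annotation releases
#'
#' The set difference of unversioned transcript identifiers: present in the
#' newer release, absent from the older one. Identifier renames upstream of
#' this comparison appear as a drop plus an addition; no identifier-history
#' resolution is attempted.
#'
#' @param old,new [annotation_release()] objects.
#' @return An object of class `new_isoform_set`: list with `old_label`,
#'   `new_label`, `transcript_ids`.
#' @export
new_isoforms <- function(old, new) {
  ids <- setdiff(id_set(new, "transcript"), id_set(old, "transcript"))
  structure(list(old_label = old$label, new_label = new$label,
                 transcript_ids = ids),
            class = "new_isoform_set")
}

#' @export
print.new_isoform_set <- function(x, ...) {
  cat("<new_isoform_set> ", x$new_label, " minus ", x$old_label, ": ",
      length(x$transcript_ids), " transcripts\n", sep = "")
  invisible(x)
}

as_id_vector <- function(x) {
  if (inherits(x, "new_isoform_set")) x$transcript_ids else as.character(x)
}

row_medians <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  apply(m, 1L, stats::median)
}

#' Per-tissue expression calls
#'
#' For each tissue, the median unique count and median CPM of every
#' transcript are computed across that tissue's samples only. A transcript
#' is called expressed in a tissue when its median count passes
#' `min_median_count` and its median CPM passes `min_median_cpm`. The
#' default comparators are strict for the count rule (`> 1`) and inclusive
#' for the CPM rule (`>= 1`); both are configurable because either boundary
#' convention is defensible.
#'
#' @param x a [counts_matrix()].
#' @param min_median_count count threshold (default 1).
#' @param min_median_cpm CPM threshold (default 1).
#' @param count_strict logical; `TRUE` uses `>` for the count rule.
#' @param cpm_strict logical; `FALSE` uses `>=` for the CPM rule.
#' @return data.frame with columns `tissue`, `transcript_id`,
#'   `median_unique_counts`, `median_cpm`, `expressed`.
#' @export
call_expressed <- function(x, min_median_count = 1, min_median_cpm = 1,
                           count_strict = TRUE, cpm_strict = FALSE) {
  stopifnot(inherits(x, "counts_matrix"))
  cpm_m <- cpm(x)
  tissues <- sort(unique(x$tissue_of))
  out <- vector("list", length(tissues))
  for (i in seq_along(tissues)) {
    smp <- names(x$tissue_of)[x$tissue_of == tissues[i]]
    if (!length(smp)) stop("tissue with zero samples: ", tissues[i])
    med_c <- row_medians(x$counts[, smp, drop = FALSE])
    med_p <- row_medians(cpm_m[, smp, drop = FALSE])
    pass_c <- if (count_strict) med_c > min_median_count else med_c >= min_median_count
    pass_p <- if (cpm_strict) med_p > min_median_cpm else med_p >= min_median_cpm
    out[[i]] <- data.frame(tissue = tissues[i],
                           transcript_id = rownames(x$counts),
                           median_unique_counts = unname(med_c),
                           median_cpm = unname(med_p),
                           expressed = unname(pass_c & pass_p),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-tissue counts of expressed new isoforms, overall and by category
#'
#' Intersects the expressed set of each tissue with the new-isoform set and,
#' optionally, with gene-category lists (e.g. medically relevant,
#' brain-disease relevant, new coding sequence). Also returns the pairwise
#' tissue overlap matrix of expressed new isoforms for Venn-style reporting.
#'
#' @param calls output of [call_expressed()].
#' @param new_set a [new_isoforms()] result or character vector of
#'   transcript identifiers.
#' @param gene_of named character vector mapping transcript identifiers to
#'   gene identifiers; required when `categories` are given.
#' @param categories named list of gene-identifier vectors. Category genes
#'   absent from `gene_of` trigger a warning, not an error.
#' @return list with `per_tissue` (data.frame of counts), `expressed_ids`
#'   (per-tissue list of expressed new transcript identifiers), and
#'   `overlaps` (tissue x tissue matrix of shared expressed new isoforms).
#' @export
count_new_expressed <- function(calls, new_set, gene_of = NULL,
                                categories = list()) {
  new_ids <- as_id_vector(new_set)
  if (length(categories) && is.null(gene_of))
    stop("gene_of is required to resolve gene-category lists")
  tissues <- sort(unique(calls$tissue))
  expressed_ids <- lapply(tissues, function(t) {
    sub <- calls[calls$tissue == t & calls$expressed, , drop = FALSE]
    intersect(sub$transcript_id, new_ids)
  })
  names(expressed_ids) <- tissues
  per_tissue <- data.frame(tissue = tissues,
                           n_new_expressed = lengths(expressed_ids),
                           stringsAsFactors = FALSE)
  for (nm in names(categories)) {
    genes <- categories[[nm]]
    missing <- setdiff(genes, gene_of)
    if (length(missing))
      warning("category '", nm, "': ", length(missing),
              " gene id(s) absent from the release mapping")
    per_tissue[[paste0("n_", nm)]] <- vapply(expressed_ids, function(ids)
      sum(gene_of[ids] %in% genes), integer(1L))
  }
  ov <- matrix(0L, length(tissues), length(tissues),
               dimnames = list(tissues, tissues))
  for (i in seq_along(tissues)) for (j in seq_along(tissues))
    ov[i, j] <- length(intersect(expressed_ids[[i]], expressed_ids[[j]]))
  list(per_tissue = per_tissue, expressed_ids = expressed_ids, overlaps = ov)
}

#' Sweep the CPM threshold for new-isoform expression counts
#'
#' Counts, per tissue, how many new isoforms pass the fixed median-count
#' rule together with a median CPM threshold, for each threshold on an
#' ascending grid. Counts are non-increasing in the threshold, and the
#' count at the default threshold reproduces [count_new_expressed()].
#'
#' @param x a [counts_matrix()].
#' @param new_set a [new_isoforms()] result or character vector.
#' @param cpm_grid ascending numeric vector of CPM thresholds.
#' @param min_median_count,count_strict,cpm_strict see [call_expressed()].
#' @return data.frame with columns `tissue`, `cpm_threshold`, `n_expressed`.
#' @export
threshold_sweep <- function(x, new_set, cpm_grid = c(0.5, 1, 2, 5, 10),
                            min_median_count = 1, count_strict = TRUE,
                            cpm_strict = FALSE) {
  stopifnot(inherits(x, "counts_matrix"))
  if (is.unsorted(cpm_grid, strictly = FALSE))
    stop("cpm_grid must be ascending")
  new_ids <- intersect(as_id_vector(new_set), rownames(x$counts))
  cpm_m <- cpm(x)
  tissues <- sort(unique(x$tissue_of))
  rows <- list()
  for (t in tissues) {
    smp <- names(x$tissue_of)[x$tissue_of == t]
    med_c <- row_medians(x$counts[new_ids, smp, drop = FALSE])
    med_p <- row_medians(cpm_m[new_ids, smp, drop = FALSE])
    pass_c <- if (count_strict) med_c > min_median_count else med_c >= min_median_count
    for (g in cpm_grid) {
      pass_p <- if (cpm_strict) med_p > g else med_p >= g
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = t, cpm_threshold = g, n_expressed = sum(pass_c & pass_p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summed relative abundance of a transcript subset per gene and tissue
#'
#' For every sample, each isoform's share of its gene is its count divided
#' by the summed counts of all the gene's isoforms in the matrix; the
#' subset's (e.g. newly annotated isoforms') summed share is then aggregated
#' per tissue. The default aggregation is the median across the tissue's
#' samples, excluding samples where the gene has zero total counts; the
#' alternative pools counts across the tissue's samples before taking the
#' ratio. A gene with zero counts in every sample of a tissue yields no
#' record for that tissue.
#'
#' @param x a [counts_matrix()] whose `gene_of` map is set.
#' @param new_set a [new_isoforms()] result or character vector of
#'   transcript identifiers (the designated subset).
#' @param genes optional gene restriction; genes absent from the matrix are
#'   dropped with a warning. Default: every gene with at least one subset
#'   transcript in the matrix.
#' @param method `"per_sample_median"` (default) or `"pooled"`.
#' @param calls optional [call_expressed()] output; when supplied, the
#'   number of subset isoforms called expressed in the tissue is reported.
#' @return data.frame with columns `gene_id`, `tissue`,
#'   `summed_relative_abundance` (in `[0, 1]`), `n_new_isoforms`, and
#'   `n_new_isoforms_expressed` (`NA` without `calls`).
#' @export
relative_abundance <- function(x, new_set, genes = NULL,
                               method = c("per_sample_median", "pooled"),
                               calls = NULL) {
  stopifnot(inherits(x, "counts_matrix"))
  method <- match.arg(method)
  if (is.null(x$gene_of))
    stop("counts_matrix has no transcript-to-gene mapping (gene_of)")
  new_ids <- intersect(as_id_vector(new_set), rownames(x$counts))
  gene_of <- x$gene_of
  if (is.null(genes)) {
    genes <- sort(unique(gene_of[new_ids]))
  } else {
    absent <- setdiff(genes, gene_of)
    if (length(absent))
      warning(length(absent), " gene(s) absent from the counts matrix: ",
              paste(utils::head(absent, 5L), collapse = ", "))
    genes <- sort(intersect(genes, gene_of))
  }
  is_new <- rownames(x$counts) %in% new_ids
  gene_tot <- rowsum(x$counts, gene_of)               # gene x sample totals
  new_tot <- rowsum(x$counts * is_new, gene_of)
  gene_tot <- gene_tot[genes, , drop = FALSE]
  new_tot <- new_tot[genes, , drop = FALSE]
  n_new_per_gene <- vapply(genes, function(g)
    sum(gene_of[new_ids] == g), integer(1L))
  tissues <- sort(unique(x$tissue_of))
  rows <- list()
  for (t in tissues) {
    smp <- names(x$tissue_of)[x$tissue_of == t]
    gt <- gene_tot[, smp, drop = FALSE]
    nt <- new_tot[, smp, drop = FALSE]
    for (k in seq_along(genes)) {
      nz <- gt[k, ] > 0
      if (!any(nz)) next  # gene silent in this tissue: no record, not 0/0
      val <- if (method == "pooled") sum(nt[k, ]) / sum(gt[k, ]) else
        stats::median(nt[k, nz] / gt[k, nz])
      n_expr <- NA_integer_
      if (!is.null(calls)) {
        sub <- calls[calls$tissue == t & calls$expressed, , drop = FALSE]
        n_expr <- sum(gene_of[intersect(sub$transcript_id, new_ids)] == genes[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[k], tissue = t, summed_relative_abundance = val,
        n_new_isoforms = n_new_per_gene[k], n_new_isoforms_expressed = n_expr,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), tissue = character(0),
                      summed_relative_abundance = numeric(0),
                      n_new_isoforms = integer(0),
                      n_new_isoforms_expressed = integer(0)))
  do.call(rbind, rows)
}

#' Genes whose subset abundance exceeds cutoffs across tissues
#'
#' For each abundance cutoff, counts genes whose summed subset abundance
#' exceeds the cutoff in every tissue they were measured in (requiring a
#' record in all tissues of the table) and genes exceeding it in at least
#' one tissue. Fractions are relative to the genes considered.
#'
#' @param records output of [relative_abundance()].
#' @param gene_subset optional gene restriction (e.g. medically relevant
#'   genes).
#' @param cutoffs numeric abundance cutoffs in `[0, 1]`.
#' @return data.frame with one row per cutoff: `cutoff`, `n_genes`,
#'   `n_all_tissues`, `frac_all_tissues`, `n_any_tissue`, `frac_any_tissue`.
#' @export
abundance_threshold_summary <- function(records, gene_subset = NULL,
                                        cutoffs = c(0.25, 0.75)) {
  if (!is.null(gene_subset))
    records <- records[records$gene_id %in% gene_subset, , drop = FALSE]
  genes <- unique(records$gene_id)
  tissues <- unique(records$tissue)
  rows <- lapply(cutoffs, function(co) {
    above <- tapply(records$summed_relative_abundance > co, records$gene_id, sum)
    seen <- tapply(rep(1L, nrow(records)), records$gene_id, sum)
    n_all <- sum(seen[genes] == length(tissues) & above[genes] == length(tissues))
    n_any <- sum(above[genes] >= 1L)
    data.frame(cutoff = co, n_genes = length(genes),
               n_all_tissues = n_all,
               frac_all_tissues = if (length(genes)) n_all / length(genes) else NA_real_,
               n_any_tissue = n_any,
               frac_any_tissue = if (length(genes)) n_any / length(genes) else NA_real_)
  })
  do.call(rbind, rows)
}
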