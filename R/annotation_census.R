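#' Per-release census of genes, transcripts, and biotypes
#'
#' Counts gene and transcript features in a release, in total and restricted
#' to the protein-coding biotype, plus full biotype breakdowns at both
#' levels. "Protein-coding" means the biotype string equals
#' `"protein_coding"` exactly; all other counts use every feature regardless
#' of biotype ("gene bodies").
#'
#' @param release an [annotation_release()].
#' @return An object of class `census_row`: a list with `release_label`,
#'   `n_genes`, `n_transcripts`, `n_protein_coding_genes`,
#'   `n_protein_coding_transcripts`, and named count vectors
#'   `gene_biotype_counts` and `transcript_biotype_counts`.
#' @export
census <- function(release) {
  stopifnot(inherits(release, "annotation_release"))
  g <- release$genes; tx <- release$transcripts
  gb <- table(g$biotype, useNA = "ifany")
  tb <- table(tx$biotype, useNA = "ifany")
  structure(list(
    release_label = release$label,
    n_genes = nrow(g),
    n_transcripts = nrow(tx),
    n_protein_coding_genes = sum(g$biotype == "protein_coding", na.rm = TRUE),
    n_protein_coding_transcripts = sum(tx$biotype == "protein_coding", na.rm = TRUE),
    gene_biotype_counts = stats::setNames(as.integer(gb), names(gb)),
    transcript_biotype_counts = stats::setNames(as.integer(tb), names(tb))
  ), class = "census_row")
}

#' @export
print.census_row <- function(x, ...) {
  cat("<census_row> ", x$release_label, ": ", x$n_genes, " genes (",
      x$n_protein_coding_genes, " protein_coding), ", x$n_transcripts,
      " transcripts (", x$n_protein_coding_transcripts, " protein_coding)\n",
      sep = "")
  invisible(x)
}

#' Census table across several releases
#'
#' @param releases list of [annotation_release()] objects.
#' @param path optional TSV output path.
#' @return data.frame with one row per release.
#' @export
census_table <- function(releases, path = NULL) {
  rows <- lapply(releases, function(r) {
    cr <- census(r)
    data.frame(release_label = cr$release_label, n_genes = cr$n_genes,
               n_transcripts = cr$n_transcripts,
               n_protein_coding_genes = cr$n_protein_coding_genes,
               n_protein_coding_transcripts = cr$n_protein_coding_transcripts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Biotype ranking for one release
#'
#' Biotype labels sorted by descending feature count; ties are broken
#' lexicographically by label so the ranking is deterministic.
#'
#' @param release an [annotation_release()].
#' @param level `"gene"` or `"transcript"`.
#' @return named integer vector, most frequent biotype first.
#' @export
biotype_ranking <- function(release, level = c("transcript", "gene")) {
  stopifnot(inherits(release, "annotation_release"))
  level <- match.arg(level)
  bio <- if (level == "gene") release$genes$biotype else release$transcripts$biotype
  cnt <- table(bio)
  cnt <- cnt[order(-as.integer(cnt), names(cnt))]
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Isoforms-per-gene distribution
#'
#' Number of annotated transcripts for each gene, with distribution
#' percentiles, the most isoform-rich gene, and the number of genes at or
#' above each of a set of thresholds. Genes that carry no transcript rows
#' count as zero-isoform genes. Percentiles use linear interpolation between
#' order statistics ([stats::quantile()] type 7, the R default).
#'
#' @param release an [annotation_release()].
#' @param gene_biotype optional gene-biotype filter (e.g. `"protein_coding"`);
#'   `NULL` keeps all gene bodies.
#' @param thresholds integer thresholds for at-or-above gene counts.
#' @param probs percentile ranks to report.
#' @return An object of class `isoforms_per_gene_summary`: list with
#'   `per_gene` (named integer vector), `percentiles`, `max_gene`
#'   (`gene_id` and `count`), `thresholded` (named counts), `n_genes`,
#'   `n_transcripts`. An empty cohort gives `n_genes = 0` with `NA`
#'   percentiles rather than an error.
#' @export
isoforms_per_gene <- function(release, gene_biotype = NULL,
                              thresholds = c(10L, 50L, 100L),
                              probs = c(0.5, 0.75, 0.85, 0.95)) {
  stopifnot(inherits(release, "annotation_release"))
  g <- release$genes
  if (!is.null(gene_biotype)) g <- g[g$biotype %in% gene_biotype, , drop = FALSE]
  empty <- structure(list(
    release_label = release$label, gene_biotype = gene_biotype,
    per_gene = stats::setNames(integer(0), character(0)),
    percentiles = stats::setNames(rep(NA_real_, length(probs)),
                                  paste0("p", probs * 100)),
    max_gene = list(gene_id = NA_character_, count = NA_integer_),
    thresholded = stats::setNames(integer(length(thresholds)),
                                  paste0(">=", thresholds)),
    n_genes = 0L, n_transcripts = 0L), class = "isoforms_per_gene_summary")
  if (!nrow(g)) return(empty)
  tx <- release$transcripts[release$transcripts$gene_id %in% g$gene_id, , drop = FALSE]
  cnt <- stats::setNames(integer(nrow(g)), g$gene_id)
  if (nrow(tx)) {
    tab <- table(tx$gene_id)
    cnt[names(tab)] <- as.integer(tab)
  }
  pct <- stats::quantile(cnt, probs = probs, type = 7, names = FALSE)
  ord <- order(-cnt, names(cnt))  # ties resolved by lexicographic gene_id
  structure(list(
    release_label = release$label, gene_biotype = gene_biotype,
    per_gene = cnt,
    percentiles = stats::setNames(pct, paste0("p", probs * 100)),
    max_gene = list(gene_id = names(cnt)[ord[1L]],
                    count = unname(cnt[ord[1L]])),
    thresholded = stats::setNames(
      vapply(thresholds, function(t) sum(cnt >= t), integer(1L)),
      paste0(">=", thresholds)),
    n_genes = length(cnt), n_transcripts = sum(cnt)
  ), class = "isoforms_per_gene_summary")
}

#' @export
print.isoforms_per_gene_summary <- function(x, ...) {
  cat("<isoforms_per_gene_summary> ", x$release_label,
      if (!is.null(x$gene_biotype)) paste0(" [", x$gene_biotype, "]"), "\n",
      sep = "")
  cat("  genes: ", x$n_genes, "  transcripts: ", x$n_transcripts, "\n", sep = "")
  if (x$n_genes) {
    cat("  percentiles: ",
        paste(names(x$percentiles), round(x$percentiles, 2), sep = "=",
              collapse = "  "), "\n", sep = "")
    cat("  max gene: ", x$max_gene$gene_id, " (", x$max_gene$count, ")\n", sep = "")
    cat("  thresholds: ",
        paste(names(x$thresholded), x$thresholded, sep = ": ", collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' JSON summary of an isoforms-per-gene distribution
#'
#' @param x an `isoforms_per_gene_summary`.
#' @param path optional JSON output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
isoforms_per_gene_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "isoforms_per_gene_summary"))
  payload <- list(release_label = x$release_label,
                  gene_biotype = x$gene_biotype,
                  n_genes = x$n_genes, n_transcripts = x$n_transcripts,
                  percentiles = as.list(x$percentiles),
                  max_gene = x$max_gene,
                  thresholded = as.list(x$thresholded))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
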