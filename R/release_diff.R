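#' Feature identifier set of a release
#'
#' The set of (unversioned) gene or transcript identifiers of one release,
#' optionally restricted to a biotype. Under a biotype filter an identifier
#' belongs to the set only if it is present AND carries that biotype in this
#' release, so a feature whose biotype changed between releases drops out of
#' the filtered set even though it is structurally present.
#'
#' @param release an [annotation_release()].
#' @param level `"gene"` or `"transcript"`.
#' @param biotype optional biotype label; `NULL` keeps every feature.
#' @return character vector of identifiers.
#' @export
id_set <- function(release, level = c("gene", "transcript"), biotype = NULL) {
  stopifnot(inherits(release, "annotation_release"))
  level <- match.arg(level)
  tab <- if (level == "gene") release$genes else release$transcripts
  ids <- if (level == "gene") tab$gene_id else tab$transcript_id
  if (!is.null(biotype)) ids <- ids[!is.na(tab$biotype) & tab$biotype %in% biotype]
  ids
}

venn_regions_3 <- function(A, B, C) {
  list(
    only_a = setdiff(A, union(B, C)),
    only_b = setdiff(B, union(A, C)),
    only_c = setdiff(C, union(A, B)),
    a_b_not_c = setdiff(intersect(A, B), C),
    a_c_not_b = setdiff(intersect(A, C), B),
    b_c_not_a = setdiff(intersect(B, C), A),
    a_b_c = intersect(intersect(A, B), C))
}

#' Two- or three-way comparison of releases
#'
#' Partitions the union of the feature identifier sets of two or three
#' releases into disjoint Venn regions (3 regions for two releases, 7 for
#' three) and reports exact membership plus cardinalities. With a
#' `biotype_filter`, membership additionally requires carrying that biotype
#' in the respective release, which is how transient biotype changes of
#' structurally stable features become visible as Venn-region members.
#'
#' @param a,b,c [annotation_release()] objects; `c` may be `NULL` for a
#'   two-way comparison.
#' @param level `"gene"` or `"transcript"`.
#' @param biotype_filter optional biotype label.
#' @return An object of class `release_diff`: list with `labels`, `level`,
#'   `biotype_filter`, `regions` (named list of identifier vectors) and
#'   `counts` (named integer vector).
#' @export
three_way_compare <- function(a, b, c = NULL,
                              level = c("gene", "transcript"),
                              biotype_filter = NULL) {
  level <- match.arg(level)
  A <- id_set(a, level, biotype_filter)
  B <- id_set(b, level, biotype_filter)
  if (is.null(c)) {
    regions <- list(only_a = setdiff(A, B), only_b = setdiff(B, A),
                    a_b = intersect(A, B))
    labels <- c(a$label, b$label)
  } else {
    C <- id_set(c, level, biotype_filter)
    regions <- venn_regions_3(A, B, C)
    labels <- c(a$label, b$label, c$label)
  }
  structure(list(labels = labels, level = level,
                 biotype_filter = biotype_filter,
                 regions = regions,
                 counts = vapply(regions, length, integer(1L))),
            class = "release_diff")
}

#' @export
print.release_diff <- function(x, ...) {
  cat("<release_diff> ", paste(x$labels, collapse = " / "), " (", x$level,
      if (!is.null(x$biotype_filter)) paste0(", ", x$biotype_filter), ")\n",
      sep = "")
  for (nm in names(x$counts))
    cat("  ", format(nm, width = 10), " ", x$counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write the per-region identifier lists and counts of a comparison
#'
#' @param diff a `release_diff`.
#' @param tsv_path path for the long-format region/identifier table.
#' @param json_path optional path for the region-count JSON.
#' @return the long table, invisibly.
#' @export
write_diff <- function(diff, tsv_path, json_path = NULL) {
  stopifnot(inherits(diff, "release_diff"))
  long <- do.call(rbind, lapply(names(diff$regions), function(nm) {
    ids <- diff$regions[[nm]]
    if (!length(ids)) return(NULL)
    data.frame(region = nm, feature_id = ids, stringsAsFactors = FALSE)
  }))
  if (is.null(long))
    long <- data.frame(region = character(0), feature_id = character(0))
  utils::write.table(long, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(as.list(diff$counts), auto_unbox = TRUE),
               json_path)
  invisible(long)
}

#' Detect transient biotype flips across three releases
#'
#' Finds features structurally present in all three releases whose
#' membership in a given biotype holds in the first and last release but
#' not in the middle one — e.g. a gene annotated protein-coding in 2019 and
#' 2023 that was re-classified as a pseudogene in 2021 and then reverted.
#' This equals the (A intersect C) minus B Venn region of the
#' biotype-filtered comparison, restricted to identifiers structurally
#' present in the middle release.
#'
#' @param a,b,c [annotation_release()] objects, in chronological order.
#' @param level `"gene"` or `"transcript"`.
#' @param biotype the biotype whose membership must flip (default
#'   `"protein_coding"`).
#' @return data.frame with columns `feature_id`, `level`, `biotype_a`,
#'   `biotype_b`, `biotype_c` (zero rows when there is no flip).
#' @export
find_biotype_flips <- function(a, b, c, level = c("gene", "transcript"),
                               biotype = "protein_coding") {
  level <- match.arg(level)
  present_b <- id_set(b, level)
  filt <- three_way_compare(a, b, c, level = level, biotype_filter = biotype)
  ids <- intersect(filt$regions$a_c_not_b, present_b)
  ids <- sort(ids)
  bio_of <- function(rel, ids) {
    tab <- if (level == "gene") rel$genes else rel$transcripts
    key <- if (level == "gene") tab$gene_id else tab$transcript_id
    tab$biotype[match(ids, key)]
  }
  data.frame(feature_id = ids,
             level = rep(level, length(ids)),
             biotype_a = bio_of(a, ids),
             biotype_b = bio_of(b, ids),
             biotype_c = bio_of(c, ids),
             stringsAsFactors = FALSE)
}
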