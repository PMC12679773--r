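#' Harmonize biotype labels into summary categories
#'
#' Maps `"lincRNA"` to `"lncRNA"` and passes every other label through
#' unchanged. Ensembl replaced the lincRNA transcript biotype with lncRNA
#' around 2020 (lincRNAs are a subset of lncRNAs), so length summaries that
#' span that change merge the two. The merge applies at summary time only;
#' raw biotypes in the release are never rewritten.
#'
#' @param biotype character vector of biotype labels.
#' @return character vector of harmonized category labels.
#' @examples
#' harmonize_biotype(c("lincRNA", "protein_coding", "retained_intron"))
#' @export
harmonize_biotype <- function(biotype) {
  ifelse(biotype == "lincRNA", "lncRNA", biotype)
}

#' N50 of a length cohort
#'
#' The assembly-statistics N50: sort the lengths in descending order and
#' return the length at which the running cumulative sum first reaches at
#' least half of the total bases. Equivalently, the largest length L in the
#' cohort such that members of length >= L together hold at least half of
#' all bases. The result is always the length of some member of the cohort
#' and does not depend on input order.
#'
#' @param lengths numeric vector of positive lengths (a multiset; repeats
#'   allowed).
#' @return single numeric length.
#' @examples
#' n50(c(100, 80, 50, 30))  # 80: cumulative 100, 180 >= 130
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 of an empty cohort is undefined")
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and non-missing")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= cs[length(cs)] / 2)[1L]]
}

#' Transcript length summary for one release and category
#'
#' Quartiles (25th, 50th, 75th percentile), N50 and total bases of the
#' exon-sum transcript lengths of all transcripts whose harmonized biotype
#' matches the requested category (`"all"` keeps every transcript).
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); the median for even cohort sizes is
#' therefore the mean of the two central order statistics.
#'
#' @param release an [annotation_release()].
#' @param category `"all"` or a harmonized biotype category (see
#'   [harmonize_biotype()]), e.g. `"protein_coding"`, `"lncRNA"`,
#'   `"retained_intron"`.
#' @return An object of class `length_summary`: list with `release_label`,
#'   `category`, `n`, `p25`, `p50`, `p75`, `n50`, `total_bases`. An empty
#'   category yields `n = 0` with `NA` statistics rather than an error.
#' @export
length_summary <- function(release, category = "all") {
  stopifnot(inherits(release, "annotation_release"))
  tx <- release$transcripts
  if (!identical(category, "all")) {
    tx <- tx[!is.na(tx$biotype) &
               harmonize_biotype(tx$biotype) == category, , drop = FALSE]
  }
  if (!nrow(tx)) {
    return(structure(list(release_label = release$label, category = category,
                          n = 0L, p25 = NA_real_, p50 = NA_real_,
                          p75 = NA_real_, n50 = NA_real_, total_bases = 0),
                     class = "length_summary"))
  }
  len <- tx$length
  q <- stats::quantile(len, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(release_label = release$label, category = category,
                 n = nrow(tx), p25 = q[1L], p50 = q[2L], p75 = q[3L],
                 n50 = n50(len), total_bases = sum(as.numeric(len))),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat("<length_summary> ", x$release_label, " [", x$category, "]: n=", x$n,
      sep = "")
  if (x$n)
    cat("  p25=", x$p25, " p50=", x$p50, " p75=", x$p75, " N50=", x$n50,
        " total=", format(x$total_bases, big.mark = ","), " b", sep = "")
  cat("\n")
  invisible(x)
}

#' Long-format length summary table across releases and categories
#'
#' @param releases list of [annotation_release()] objects.
#' @param categories harmonized categories to summarize; `"all"` is the
#'   whole-release aggregate.
#' @param path optional TSV output path.
#' @return data.frame with one row per release x category.
#' @export
length_summary_table <- function(releases,
                                 categories = c("all", "protein_coding",
                                                "lncRNA", "retained_intron"),
                                 path = NULL) {
  rows <- list()
  for (rel in releases) for (cat_i in categories) {
    s <- length_summary(rel, cat_i)
    rows[[length(rows) + 1L]] <- data.frame(
      release_label = s$release_label, category = s$category, n = s$n,
      p25 = s$p25, p50 = s$p50, p75 = s$p75, n50 = s$n50,
      total_bases = s$total_bases, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
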