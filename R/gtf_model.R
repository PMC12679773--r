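#' @title Annotation release container
#'
#' @description An `annotation_release` holds the parsed gene -> transcript ->
#' exon hierarchy of one annotation release (one GTF file), together with a
#' release label and a record of which contigs were kept. It is the input to
#' every census, comparison, and length statistic in the package.
#'
#' @details Coordinates follow the GTF convention: 1-based, fully closed, so a
#' feature spanning positions `start..end` has length `end - start + 1`.
#' Feature identifiers are stored without their trailing version suffix
#' (`ENSG00000000001.3` becomes `ENSG00000000001`) so that identifiers can be
#' compared across releases whose version numbers differ. Strand is carried
#' through but no statistic in the package uses it.
#'
#' @param label single string naming the release (e.g. `"v109"` or `"2023"`).
#' @param genes data.frame with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype`, `chrom`, `strand`, `length`, `n_exons`.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; one row per exon.
#' @param contig_policy character vector of kept contig names, or `"all"`.
#' @param provenance named list of free-form parsing notes (e.g. whether the
#'   transcript biotype was read from an attribute or fell back to the GTF
#'   source column).
#'
#' @return An object of class `annotation_release`.
#' @export
annotation_release <- function(label, genes, transcripts, exons,
                               contig_policy = "all", provenance = list()) {
  stopifnot(is.character(label), length(label) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  obj <- structure(
    list(label = label, genes = genes, transcripts = transcripts,
         exons = exons, contig_policy = contig_policy,
         provenance = provenance),
    class = "annotation_release")
  validate_release(obj)
  obj
}

#' Validate an annotation release
#'
#' Checks the structural invariants of the container: unique gene and
#' transcript identifiers, every transcript resolving to a known gene, at
#' least one exon per transcript, positive exon lengths, and exons of one
#' transcript sharing a contig and strand.
#'
#' @param x an `annotation_release`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_release <- function(x) {
  stopifnot(inherits(x, "annotation_release"))
  g <- x$genes; tx <- x$transcripts; ex <- x$exons
  need_g <- c("gene_id", "gene_name", "biotype", "chrom", "start", "end", "strand")
  need_t <- c("transcript_id", "gene_id", "biotype", "chrom", "strand",
              "length", "n_exons")
  need_e <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need_g %in% names(g)))
    stop("genes table is missing columns: ",
         paste(setdiff(need_g, names(g)), collapse = ", "))
  if (!all(need_t %in% names(tx)))
    stop("transcripts table is missing columns: ",
         paste(setdiff(need_t, names(tx)), collapse = ", "))
  if (!all(need_e %in% names(ex)))
    stop("exons table is missing columns: ",
         paste(setdiff(need_e, names(ex)), collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in release '", x$label, "': ",
         g$gene_id[duplicated(g$gene_id)][1L])
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in release '", x$label, "': ",
         tx$transcript_id[duplicated(tx$transcript_id)][1L])
  orphan <- setdiff(tx$gene_id, g$gene_id)
  if (length(orphan))
    stop("transcript(s) reference gene_id(s) never seen as a gene feature in ",
         "release '", x$label, "': ", paste(utils::head(orphan, 5L), collapse = ", "))
  if (nrow(ex)) {
    if (any(ex$end < ex$start))
      stop("exon with end < start in release '", x$label, "'")
    if (any(ex$start < 1L))
      stop("exon with start < 1 in release '", x$label, "'")
    bad_tx <- setdiff(unique(ex$transcript_id), tx$transcript_id)
    if (length(bad_tx))
      stop("exon(s) reference unknown transcript_id(s): ",
           paste(utils::head(bad_tx, 5L), collapse = ", "))
  }
  if (nrow(tx) && any(tx$n_exons < 1L))
    stop("transcript without exons in release '", x$label, "': ",
         tx$transcript_id[tx$n_exons < 1L][1L])
  invisible(x)
}

#' @export
print.annotation_release <- function(x, ...) {
  cat("<annotation_release> ", x$label, "\n", sep = "")
  cat("  genes:       ", nrow(x$genes), "\n", sep = "")
  cat("  transcripts: ", nrow(x$transcripts), "\n", sep = "")
  cat("  exons:       ", nrow(x$exons), "\n", sep = "")
  pol <- if (identical(x$contig_policy, "all")) "all contigs" else
    paste0(length(x$contig_policy), " allowed contigs")
  cat("  contigs:     ", pol, "\n", sep = "")
  invisible(x)
}

#' Default contig allowlist: the primary human chromosomes
#'
#' The primary assembly chromosomes 1-22, X, Y and MT. Alternative contigs
#' (haplotype and patch sequences), which older releases carry in larger
#' numbers, are excluded from all censuses by default.
#'
#' @return character vector of contig names.
#' @export
primary_contigs <- function() c(as.character(1:22), "X", "Y", "MT")

strip_id_version <- function(ids) sub("\\.[0-9]+$", "", ids)

## Cheap structural scan so malformed input is reported with a line number
## before the heavyweight importer runs.
check_gtf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 200000L)
    if (!length(chunk)) break
    keep <- !startsWith(chunk, "#") & nzchar(chunk)
    if (any(keep)) {
      body <- chunk[keep]
      ntab <- nchar(body) - nchar(gsub("\t", "", body, fixed = TRUE))
      bad <- which(ntab != 8L)
      if (length(bad)) {
        line_no <- n + which(keep)[bad[1L]]
        stop("malformed GTF line ", line_no, " in '", path,
             "': expected 9 tab-separated fields, found ", ntab[bad[1L]] + 1L)
      }
    }
    n <- n + length(chunk)
  }
  invisible(TRUE)
}

#' Parse a GTF file into an annotation release
#'
#' Reads an Ensembl-dialect GTF (optionally gzip-compressed) and builds the
#' validated gene/transcript/exon hierarchy used by all downstream analyses.
#' Identifier version suffixes (`".N"`) are stripped, and features on contigs
#' outside the allowlist are dropped before any counting.
#'
#' @details Gene and transcript biotypes are taken from the `gene_biotype`
#' and `transcript_biotype` attributes. Some older release dialects omit
#' `transcript_biotype`; in that case the GTF source column (column 2) is
#' used as the transcript biotype and the fallback is recorded in the
#' release's `provenance`. Parsing is delegated to
#' [rtracklayer::import()]; a light structural scan runs first so a
#' malformed line is reported with its line number.
#'
#' @param path path to a GTF file (plain or `.gz`).
#' @param contig_allowlist character vector of contig names to keep, or
#'   `"all"` to keep everything. Defaults to [primary_contigs()].
#' @param label release label; defaults to the file name.
#' @return An [annotation_release()].
#' @examples
#' gtf <- system.file("extdata", "mini_release.gtf", package = "annotrack")
#' rel <- parse_gtf(gtf, label = "demo")
#' rel
#' @export
parse_gtf <- function(path, contig_allowlist = primary_contigs(),
                      label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id") %in% names(m)))
    stop("unrecognized GTF attribute dialect in '", path,
         "': required attributes (gene_id) not found; ",
         "check that attributes are formatted as key \"value\"; pairs")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- if (identical(contig_allowlist, "all")) rep(TRUE, length(gr)) else
    chrom %in% contig_allowlist
  gr <- gr[keep]; m <- m[keep, , drop = FALSE]; chrom <- chrom[keep]

  type <- as.character(m$type)
  provenance <- list()

  is_g <- type == "gene"
  is_t <- type == "transcript"
  is_e <- type == "exon"
  if (!any(is_g) || !any(is_t))
    stop("GTF '", path, "' contains no gene or transcript features; ",
         "only the Ensembl dialect with explicit gene/transcript rows is supported")

  gname <- if ("gene_name" %in% names(m)) as.character(m$gene_name) else
    rep(NA_character_, length(gr))
  gbio <- if ("gene_biotype" %in% names(m)) as.character(m$gene_biotype) else
    rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = strip_id_version(as.character(m$gene_id[is_g])),
    gene_name = gname[is_g],
    biotype = gbio[is_g],
    chrom = chrom[is_g],
    start = GenomicRanges::start(gr)[is_g],
    end = GenomicRanges::end(gr)[is_g],
    strand = as.character(GenomicRanges::strand(gr))[is_g],
    stringsAsFactors = FALSE)

  if ("transcript_biotype" %in% names(m) &&
      !all(is.na(m$transcript_biotype[is_t]))) {
    tbio <- as.character(m$transcript_biotype)[is_t]
  } else {
    tbio <- as.character(m$source)[is_t]
    provenance$transcript_biotype_fallback <- "source_column"
  }
  tx_ids <- strip_id_version(as.character(m$transcript_id[is_t]))
  exons <- data.frame(
    transcript_id = strip_id_version(as.character(m$transcript_id[is_e])),
    chrom = chrom[is_e],
    start = GenomicRanges::start(gr)[is_e],
    end = GenomicRanges::end(gr)[is_e],
    strand = as.character(GenomicRanges::strand(gr))[is_e],
    stringsAsFactors = FALSE)
  exlen <- exons$end - exons$start + 1L
  len_by_tx <- rowsum(exlen, exons$transcript_id)
  n_by_tx <- rowsum(rep(1L, nrow(exons)), exons$transcript_id)
  idx <- match(tx_ids, rownames(len_by_tx))
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = strip_id_version(as.character(m$gene_id[is_t])),
    biotype = tbio,
    chrom = chrom[is_t],
    strand = as.character(GenomicRanges::strand(gr))[is_t],
    length = as.integer(len_by_tx[idx, 1L]),
    n_exons = as.integer(n_by_tx[idx, 1L]),
    stringsAsFactors = FALSE)
  transcripts$length[is.na(transcripts$length)] <- 0L
  transcripts$n_exons[is.na(transcripts$n_exons)] <- 0L

  annotation_release(label = label, genes = genes, transcripts = transcripts,
                     exons = exons,
                     contig_policy = contig_allowlist,
                     provenance = provenance)
}

#' Transcript length from its exons
#'
#' The length of a transcript is the sum of the lengths of its exons, each
#' exon contributing `end - start + 1` bases (GTF coordinates are 1-based
#' and fully closed). The result does not depend on the order the exons are
#' given in.
#'
#' @param exons data.frame with numeric columns `start` and `end` (one row
#'   per exon), or an `annotation_release` when `transcript_id` is given.
#' @param transcript_id when `exons` is a release: identifier(s) of the
#'   transcript(s) to measure.
#' @return integer vector of lengths in bases.
#' @examples
#' transcript_length(data.frame(start = c(100, 300), end = c(199, 349)))
#' @export
transcript_length <- function(exons, transcript_id = NULL) {
  if (inherits(exons, "annotation_release")) {
    rel <- exons
    if (is.null(transcript_id)) stop("transcript_id required when passing a release")
    idx <- match(transcript_id, rel$transcripts$transcript_id)
    if (anyNA(idx))
      stop("unknown transcript_id: ",
           paste(transcript_id[is.na(idx)], collapse = ", "))
    return(rel$transcripts$length[idx])
  }
  stopifnot(all(c("start", "end") %in% names(exons)))
  if (any(exons$end < exons$start)) stop("exon with end < start")
  as.integer(sum(exons$end - exons$start + 1))
}

gtf_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) all(is.na(v)), logical(1L))]
  parts <- mapply(function(k, v) paste0(k, ' "', v, '";'), names(kv), kv,
                  SIMPLIFY = TRUE)
  paste(parts, collapse = " ")
}

#' Write an annotation release back to GTF
#'
#' Emits gene, transcript, and exon rows in the Ensembl attribute dialect
#' (`key "value";` pairs). Re-parsing the written file recovers identical
#' identifier sets, biotypes, and exon coordinates, which is the round-trip
#' contract the test suite enforces. Used by the synthetic release
#' generator; a hand-kept writer keeps attribute order and quoting under
#' exact control.
#'
#' @param release an `annotation_release`.
#' @param path output file path (plain text; a `.gz` suffix writes gzip).
#' @param source_label value of the GTF source column (column 2).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(release, path, source_label = "annotrack") {
  stopifnot(inherits(release, "annotation_release"))
  g <- release$genes; tx <- release$transcripts; ex <- release$exons
  lines <- character(0)
  if (nrow(g)) {
    ga <- vapply(seq_len(nrow(g)), function(i)
      gtf_attr(gene_id = g$gene_id[i], gene_name = g$gene_name[i],
               gene_biotype = g$biotype[i]), character(1L))
    lines <- c(lines, paste(g$chrom, source_label, "gene", g$start, g$end,
                            ".", g$strand, ".", ga, sep = "\t"))
  }
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    gidx <- match(tx$gene_id[i], g$gene_id)
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    ta <- gtf_attr(gene_id = tx$gene_id[i], transcript_id = tid,
                   gene_biotype = g$biotype[gidx],
                   transcript_biotype = tx$biotype[i])
    lines <- c(lines, paste(tx$chrom[i], source_label, "transcript",
                            min(e$start), max(e$end), ".", tx$strand[i], ".",
                            ta, sep = "\t"))
    if (nrow(e)) {
      ea <- vapply(seq_len(nrow(e)), function(j)
        gtf_attr(gene_id = tx$gene_id[i], transcript_id = tid,
                 exon_number = j,
                 gene_biotype = g$biotype[gidx],
                 transcript_biotype = tx$biotype[i]), character(1L))
      lines <- c(lines, paste(e$chrom, source_label, "exon", e$start, e$end,
                              ".", e$strand, ".", ea, sep = "\t"))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(c("#!annotrack GTF export", lines), con)
  close(con)
  invisible(path)
}

#' Normalized per-transcript summary of a release
#'
#' One row per transcript: identifiers, gene and transcript biotype, exon-sum
#' length and exon count. This is the flat table downstream tools exchange.
#'
#' @param release an `annotation_release`.
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame (invisibly when `path` is given).
#' @export
release_summary <- function(release, path = NULL) {
  stopifnot(inherits(release, "annotation_release"))
  tx <- release$transcripts
  gidx <- match(tx$gene_id, release$genes$gene_id)
  out <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    gene_biotype = release$genes$biotype[gidx],
    transcript_biotype = tx$biotype,
    length = tx$length,
    n_exons = tx$n_exons,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
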