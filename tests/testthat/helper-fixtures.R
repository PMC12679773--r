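# In-code fixtures: small releases built directly from tables, so tests do
# not depend on file parsing unless parsing is the thing under test.

make_release <- function(label, genes, ...) {
  # genes: named list gene_id -> list(biotype=, chrom=, transcripts=list(
  #   transcript_id -> list(biotype=, exons=data.frame(start,end))))
  g_rows <- list(); t_rows <- list(); e_rows <- list()
  for (gid in names(genes)) {
    spec <- genes[[gid]]
    chrom <- spec$chrom %||% "1"
    strand <- spec$strand %||% "+"
    starts <- c(); ends <- c()
    for (tid in names(spec$transcripts)) {
      tsp <- spec$transcripts[[tid]]
      ex <- tsp$exons
      starts <- c(starts, ex$start); ends <- c(ends, ex$end)
      t_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid,
        biotype = tsp$biotype %||% "protein_coding",
        chrom = chrom, strand = strand,
        length = sum(ex$end - ex$start + 1L), n_exons = nrow(ex),
        stringsAsFactors = FALSE)
      e_rows[[tid]] <- data.frame(transcript_id = tid, chrom = chrom,
                                  start = ex$start, end = ex$end,
                                  strand = strand, stringsAsFactors = FALSE)
    }
    g_rows[[gid]] <- data.frame(
      gene_id = gid, gene_name = spec$name %||% NA_character_,
      biotype = spec$biotype %||% "protein_coding", chrom = chrom,
      start = min(starts), end = max(ends), strand = strand,
      stringsAsFactors = FALSE)
  }
  annotation_release(label, do.call(rbind, g_rows), do.call(rbind, t_rows),
                     do.call(rbind, e_rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one exon chain helper
ex_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

# a small two-gene release used across tests
toy_release <- function(label = "toy") {
  make_release(label, list(
    GA = list(biotype = "protein_coding", chrom = "1", name = "ALPHA",
              transcripts = list(
                TA1 = list(biotype = "protein_coding",
                           exons = ex_df(100, 199, 300, 349)),
                TA2 = list(biotype = "retained_intron",
                           exons = ex_df(100, 349)))),
    GB = list(biotype = "lincRNA", chrom = "2", name = "BETA",
              transcripts = list(
                TB1 = list(biotype = "lincRNA",
                           exons = ex_df(500, 999))))))
}

# build a release with explicit per-gene isoform counts, all constant-length
release_with_isoform_counts <- function(counts, biotype = "protein_coding",
                                        tx_len = 100L) {
  genes <- list()
  for (i in seq_along(counts)) {
    txs <- list()
    for (k in seq_len(counts[i])) {
      txs[[sprintf("T%03d_%02d", i, k)]] <-
        list(biotype = biotype, exons = ex_df(1000 * k, 1000 * k + tx_len - 1L))
    }
    genes[[sprintf("G%03d", i)]] <- list(biotype = biotype, transcripts = txs)
  }
  make_release("counts", genes)
}

# small counts_matrix fixture: 2 tissues x 2 samples
toy_counts <- function() {
  m <- rbind(t_new = c(30, 34, 2, 2),
             t_old = c(10, 10, 18, 22),
             t_off = c(1, 1, 0, 1))
  colnames(m) <- c("brain_1", "brain_2", "liver_1", "liver_2")
  counts_matrix(m,
                tissue_of = c(brain_1 = "brain", brain_2 = "brain",
                              liver_1 = "liver", liver_2 = "liver"),
                gene_of = c(t_new = "G1", t_old = "G1", t_off = "G2"))
}
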