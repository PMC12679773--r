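test_that("cpm rescales each sample to one million and preserves zeros", {
  m <- cbind(s1 = c(1, 1), s2 = c(3, 1))
  rownames(m) <- c("t1", "t2")
  p <- cpm(m)
  expect_equal(unname(p[, "s1"]), c(5e5, 5e5))
  m2 <- rbind(m, t3 = c(0, 0))
  expect_equal(unname(cpm(m2)["t3", ]), c(0, 0))
  set.seed(2)
  r <- matrix(rpois(300, 5) + 1, 50, 6,
              dimnames = list(paste0("t", 1:50), paste0("s", 1:6)))
  expect_equal(unname(colSums(cpm(r))), rep(1e6, 6))
  bad <- r; bad[, 3] <- 0
  expect_error(cpm(bad), "s3")
})

test_that("new_isoforms is the unversioned transcript set difference", {
  old <- toy_release("v_old")
  new <- toy_release("v_new")
  extra <- data.frame(transcript_id = c("TX9", "TX10"), gene_id = "GA",
                      biotype = "protein_coding", chrom = "1", strand = "+",
                      length = 100L, n_exons = 1L, stringsAsFactors = FALSE)
  new$transcripts <- rbind(new$transcripts, extra)
  new$exons <- rbind(new$exons, data.frame(
    transcript_id = c("TX9", "TX10"), chrom = "1", start = c(1L, 200L),
    end = c(100L, 299L), strand = "+", stringsAsFactors = FALSE))
  ns <- new_isoforms(old, new)
  expect_setequal(ns$transcript_ids, c("TX9", "TX10"))
  expect_length(new_isoforms(old, old)$transcript_ids, 0L)
  # disjoint from the old release by construction
  expect_length(intersect(ns$transcript_ids, id_set(old, "transcript")), 0L)
})

test_that("call_expressed applies per-tissue medians with the strict count rule", {
  cm <- toy_counts()
  calls <- call_expressed(cm)
  get <- function(t, id, col)
    calls[calls$tissue == t & calls$transcript_id == id, col]
  # brain medians for t_new: counts 32, cpm >> 1 -> expressed
  expect_true(get("brain", "t_new", "expressed"))
  # counts (1, 1): median 1 fails the strict > 1 rule even though CPM passes
  expect_false(get("brain", "t_off", "expressed"))
  # t_new in liver: counts (2, 2) pass, CPM = 1e5 passes
  expect_true(get("liver", "t_new", "expressed"))
  # inclusive count comparator flips the boundary row
  calls2 <- call_expressed(cm, count_strict = FALSE)
  expect_true(calls2[calls2$tissue == "brain" &
                       calls2$transcript_id == "t_off", "expressed"])
})

test_that("count_new_expressed intersects calls with the new set and categories", {
  cm <- toy_counts()
  calls <- call_expressed(cm)
  res <- count_new_expressed(calls, c("t_new", "t_off"),
                             gene_of = cm$gene_of,
                             categories = list(medical = "G1"))
  pt <- res$per_tissue
  expect_equal(pt$n_new_expressed[pt$tissue == "brain"], 1L)
  expect_equal(pt$n_medical[pt$tissue == "brain"], 1L)
  expect_equal(unname(res$overlaps["brain", "liver"]), 1L)  # t_new in both
  # empty new set -> zero everywhere
  res0 <- count_new_expressed(calls, character(0))
  expect_true(all(res0$per_tissue$n_new_expressed == 0L))
  # unknown category genes warn rather than fail
  expect_warning(count_new_expressed(calls, "t_new", gene_of = cm$gene_of,
                                     categories = list(med = c("G1", "GZZ"))),
                 "absent")
})

test_that("threshold_sweep is non-increasing and agrees with the default call", {
  g <- generate_counts(counts_script(seed = 5))
  grid <- c(0.5, 1, 2, 5, 10, 1e9)
  sw <- threshold_sweep(g$cm, g$new_ids, cpm_grid = grid)
  for (t in unique(sw$tissue)) {
    v <- sw$n_expressed[sw$tissue == t]
    expect_true(all(diff(v) <= 0))
    expect_equal(v[length(v)], 0L)  # effectively infinite threshold
  }
  calls <- call_expressed(g$cm)
  ref <- count_new_expressed(calls, g$new_ids)$per_tissue
  at1 <- sw[sw$cpm_threshold == 1, ]
  expect_equal(at1$n_expressed[match(ref$tissue, at1$tissue)],
               unname(ref$n_new_expressed))
  expect_error(threshold_sweep(g$cm, g$new_ids, cpm_grid = c(2, 1)),
               "ascending")
})

test_that("relative abundance recovers fixed ratios and conserves shares", {
  cm <- toy_counts()
  # G1 in brain: new/total per sample = 30/40, 34/44 -> median 0.7613...
  ra <- relative_abundance(cm, "t_new")
  v <- ra$summed_relative_abundance[ra$gene_id == "G1" & ra$tissue == "brain"]
  expect_equal(v, median(c(30 / 40, 34 / 44)))
  # a gene whose only isoform is new has abundance 1
  ra2 <- relative_abundance(cm, c("t_new", "t_off"))
  expect_equal(ra2$summed_relative_abundance[ra2$gene_id == "G2" &
                                               ra2$tissue == "brain"], 1)
  # 3:1 new:old in every sample -> 0.75 under both aggregation methods
  m <- rbind(a_new = c(30, 60), a_old = c(10, 20))
  colnames(m) <- c("x_1", "x_2")
  cm3 <- counts_matrix(m, c(x_1 = "x", x_2 = "x"),
                       gene_of = c(a_new = "GA", a_old = "GA"))
  expect_equal(relative_abundance(cm3, "a_new")$summed_relative_abundance, 0.75)
  expect_equal(relative_abundance(cm3, "a_new",
                                  method = "pooled")$summed_relative_abundance,
               0.75)
  # restricting to a gene absent from the matrix warns and omits the record
  expect_warning(ra3 <- relative_abundance(cm, "t_new", genes = c("G1", "GX")),
                 "absent")
  expect_setequal(ra3$gene_id, "G1")
})

test_that("new and old shares sum to one wherever the gene is expressed", {
  g <- generate_counts(counts_script(seed = 8))
  cm <- g$cm
  new_share <- relative_abundance(cm, g$new_ids)
  old_ids <- setdiff(rownames(cm$counts), g$new_ids)
  old_share <- relative_abundance(cm, old_ids,
                                  genes = unique(new_share$gene_id))
  m <- merge(new_share, old_share, by = c("gene_id", "tissue"))
  tot <- m$summed_relative_abundance.x + m$summed_relative_abundance.y
  # per-sample shares are complementary, and the sample median satisfies
  # median(1 - x) = 1 - median(x), so the tissue aggregates sum to exactly 1
  expect_equal(tot, rep(1, length(tot)), tolerance = 1e-12)
  # per-sample conservation, checked directly on the count totals
  gene_tot <- rowsum(cm$counts, cm$gene_of)
  new_tot <- rowsum(cm$counts * (rownames(cm$counts) %in% g$new_ids), cm$gene_of)
  nz <- gene_tot > 0
  resid <- abs((new_tot[nz] / gene_tot[nz]) +
                 ((gene_tot[nz] - new_tot[nz]) / gene_tot[nz]) - 1)
  expect_lt(max(resid), 1e-12)
})

test_that("abundance_threshold_summary counts all-tissue and any-tissue exceedances", {
  rec <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    tissue = rep(c("ta", "tb"), 3),
    summed_relative_abundance = c(0.9, 0.8, 0.3, 0.1, 0.05, 0.04))
  s <- abundance_threshold_summary(rec, cutoffs = c(0.25, 0.75))
  expect_equal(s$n_all_tissues, c(1L, 1L))   # g1 only
  expect_equal(s$n_any_tissue, c(2L, 1L))    # g1, g2 above 0.25 somewhere
  expect_equal(s$frac_all_tissues, c(1 / 3, 1 / 3))
  # cutoff 0: every measured gene counts in the any-tissue column
  s0 <- abundance_threshold_summary(rec, cutoffs = 0)
  expect_equal(s0$n_any_tissue, 3L)
  # gene subset restriction
  s1 <- abundance_threshold_summary(rec, gene_subset = c("g1", "g2"),
                                    cutoffs = 0.25)
  expect_equal(s1$n_genes, 2L)
  expect_equal(s1$n_all_tissues, 1L)
})

test_that("counts matrices round-trip through TSV and MTX readers", {
  g <- generate_counts(counts_script(n_genes = 5L, n_background = 3L,
                                     n_boundary = 2L,
                                     tissues = c(brain = 3L, liver = 3L),
                                     seed = 4))
  cm <- g$cm
  d <- tempfile(); dir.create(d)
  tsv <- file.path(d, "counts.tsv")
  utils::write.table(data.frame(transcript_id = rownames(cm$counts),
                                cm$counts, check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tmap <- file.path(d, "tissues.tsv")
  utils::write.table(data.frame(sample_id = names(cm$tissue_of),
                                tissue = unname(cm$tissue_of)),
                     tmap, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts_matrix(tsv, tmap)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$tissue_of, cm$tissue_of)
  mtx <- file.path(d, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), mtx)
  writeLines(rownames(cm$counts), file.path(d, "rows.txt"))
  writeLines(colnames(cm$counts), file.path(d, "cols.txt"))
  back2 <- read_counts_matrix(mtx, tmap, mtx_rows = file.path(d, "rows.txt"),
                              mtx_cols = file.path(d, "cols.txt"))
  expect_equal(unname(back2$counts), unname(cm$counts))
  # gene lists: one id per line, comments ignored
  gl <- file.path(d, "genes.txt")
  writeLines(c("# medically relevant", "G1", "", "G2"), gl)
  expect_equal(read_gene_list(gl), c("G1", "G2"))
})
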