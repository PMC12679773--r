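test_that("a scripted gene drop lands in the only-release-1 Venn region", {
  sc <- release_script(n_genes = 5, events = list(
    list(drop_gene = "SYNG00002"), list()), seed = 2)
  out <- generate_release_series(sc)
  expect_true("SYNG00002" %in% out$truth$venn_gene$only_a)
  d <- three_way_compare(out$releases[[1]], out$releases[[2]],
                         out$releases[[3]], level = "gene")
  expect_true("SYNG00002" %in% d$regions$only_a)
})

test_that("a scripted reverting flip is recovered by find_biotype_flips", {
  sc <- release_script(n_genes = 6, events = list(
    list(flip_biotype = list(list(id = "SYNG00004", level = "gene",
                                  to = "TEC_flipped", revert = TRUE))),
    list()), seed = 3)
  out <- generate_release_series(sc)
  fl <- out$truth$flips[[1]]
  expect_equal(fl$id, "SYNG00004")
  got <- find_biotype_flips(out$releases[[1]], out$releases[[2]],
                            out$releases[[3]], "gene", biotype = fl$from)
  expect_equal(got$feature_id, "SYNG00004")
  expect_equal(got$biotype_b, "TEC_flipped")
  expect_equal(got$biotype_a, got$biotype_c)
})

test_that("an inconsistent script errors before any file is written", {
  d <- tempfile("series"); dir.create(d)
  sc <- release_script(n_genes = 3, events = list(
    list(drop_gene = "SYNG09999"), list()), seed = 1)
  expect_error(generate_release_series(sc, dir = d), "absent id")
  expect_length(list.files(d), 0L)
  # a flip at the final step has no later release to revert in
  sc2 <- release_script(n_genes = 3, events = list(
    list(), list(flip_biotype = list(list(id = "SYNG00001", level = "gene",
                                          to = "x", revert = TRUE)))),
    seed = 1)
  expect_error(generate_release_series(sc2), "final step")
})

test_that("the same seed reproduces byte-identical GTF files", {
  sc <- release_script(n_genes = 8, events = list(
    list(add_gene = 2), list(drop_gene = "SYNG00001")), seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  o1 <- generate_release_series(sc, dir = d1)
  o2 <- generate_release_series(sc, dir = d2)
  for (k in seq_along(o1$gtf_paths))
    expect_identical(readLines(o1$gtf_paths[[k]]), readLines(o2$gtf_paths[[k]]))
})

test_that("written GTFs parse back to the primary-contig releases", {
  sc <- release_script(n_genes = 6, n_alt_contig_genes = 2,
                       events = list(list(add_gene = 1), list()), seed = 13)
  d <- tempfile()
  out <- generate_release_series(sc, dir = d)
  for (k in 1:3) {
    parsed <- parse_gtf(out$gtf_paths[[k]], label = out$releases[[k]]$label)
    expect_setequal(id_set(parsed, "gene"), id_set(out$releases[[k]], "gene"))
    expect_setequal(id_set(parsed, "transcript"),
                    id_set(out$releases[[k]], "transcript"))
    # the files do carry the alternative contig, the parse drops it
    full_genes <- id_set(out$full_releases[[k]], "gene")
    expect_gt(length(full_genes), length(id_set(parsed, "gene")))
  }
})

test_that("clamped counts make every planted call deterministic", {
  g <- generate_counts(counts_script(seed = 21))
  cm <- g$cm
  cpm_m <- cpm(cm)
  for (t in names(g$truth$expressed)) {
    smp <- names(cm$tissue_of)[cm$tissue_of == t]
    on <- g$truth$expressed[[t]]
    med_c <- apply(cm$counts[on, smp, drop = FALSE], 1, median)
    med_p <- apply(cpm_m[on, smp, drop = FALSE], 1, median)
    expect_true(all(med_c > 1 & med_p >= 1))
    off <- setdiff(rownames(cm$counts), on)
    off <- setdiff(off, g$plan$abundance_transcripts)
    expect_true(all(apply(cm$counts[off, smp, drop = FALSE], 1, median) <= 1))
  }
  # boundary rows sit at exactly one count everywhere and always fail
  expect_true(all(cm$counts[g$plan$boundary, ] == 1))
})

test_that("changing the seed changes counts but never the clamped truth", {
  g1 <- generate_counts(counts_script(seed = 31))
  g2 <- generate_counts(counts_script(seed = 32))
  expect_false(identical(g1$cm$counts, g2$cm$counts))
  expect_identical(g1$truth$expressed, g2$truth$expressed)
  expect_identical(g1$truth$abundance, g2$truth$abundance)
  expect_identical(sort(g1$new_ids), sort(g2$new_ids))
})

test_that("unclamped mode leaves raw overdispersed draws", {
  g <- generate_counts(counts_script(seed = 41, clamp = FALSE,
                                     n_genes = 10L))
  cnt <- g$cm$counts[g$plan$gene_of[rownames(g$cm$counts)] %in%
                       sprintf("SYNG%05d", 1:10), ]
  # negative-binomial draws at mean 50 / size 2 are visibly overdispersed
  expressed_vals <- cnt[cnt > 5]
  expect_gt(var(expressed_vals) / mean(expressed_vals), 2)
})
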