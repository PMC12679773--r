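test_that("three identical releases put everything in the triple intersection", {
  r <- toy_release()
  d <- three_way_compare(r, r, r, level = "gene")
  expect_equal(unname(d$counts["a_b_c"]), nrow(r$genes))
  expect_true(all(d$counts[names(d$counts) != "a_b_c"] == 0L))
})

test_that("Venn regions are disjoint and cover the union, matching per-id enumeration", {
  set.seed(5)
  for (i in 1:10) {
    plan <- random_release_script(seed = 100 + i)
    out <- generate_random_series(plan)
    rel <- out$releases
    for (level in c("gene", "transcript")) {
      d <- three_way_compare(rel[[1]], rel[[2]], rel[[3]], level = level)
      ids <- unlist(d$regions, use.names = FALSE)
      expect_false(anyDuplicated(ids) > 0)
      expect_setequal(ids, unique(c(id_set(rel[[1]], level),
                                    id_set(rel[[2]], level),
                                    id_set(rel[[3]], level))))
      oracle <- venn_enumerate(id_set(rel[[1]], level),
                               id_set(rel[[2]], level),
                               id_set(rel[[3]], level))
      for (nm in names(oracle))
        expect_setequal(d$regions[[nm]], oracle[[nm]])
    }
  }
})

test_that("swapping the outer releases maps regions symmetrically", {
  out <- generate_random_series(random_release_script(seed = 77))
  rel <- out$releases
  d1 <- three_way_compare(rel[[1]], rel[[2]], rel[[3]], level = "transcript")
  d2 <- three_way_compare(rel[[3]], rel[[2]], rel[[1]], level = "transcript")
  expect_setequal(d1$regions$only_a, d2$regions$only_c)
  expect_setequal(d1$regions$a_b_not_c, d2$regions$b_c_not_a)
  expect_setequal(d1$regions$a_c_not_b, d2$regions$a_c_not_b)
  expect_setequal(d1$regions$a_b_c, d2$regions$a_b_c)
})

test_that("a biotype filter moves re-biotyped features out of a release's set", {
  a <- toy_release("a"); b <- toy_release("b"); c <- toy_release("c")
  b$genes$biotype[b$genes$gene_id == "GA"] <- "transcribed_unprocessed_pseudogene"
  d <- three_way_compare(a, b, c, level = "gene",
                         biotype_filter = "protein_coding")
  expect_equal(d$regions$a_c_not_b, "GA")
  # structurally the gene is present everywhere
  d0 <- three_way_compare(a, b, c, level = "gene")
  expect_equal(unname(d0$counts["a_c_not_b"]), 0L)
})

test_that("find_biotype_flips returns scripted flips with the biotype triple", {
  a <- toy_release("a"); b <- toy_release("b"); c <- toy_release("c")
  b$genes$biotype[b$genes$gene_id == "GA"] <- "transcribed_unprocessed_pseudogene"
  fl <- find_biotype_flips(a, b, c, level = "gene", biotype = "protein_coding")
  expect_equal(fl$feature_id, "GA")
  expect_equal(fl$biotype_a, "protein_coding")
  expect_equal(fl$biotype_b, "transcribed_unprocessed_pseudogene")
  expect_equal(fl$biotype_c, "protein_coding")
  # a gene absent from the middle release is a drop, not a flip
  b2 <- toy_release("b2")
  b2$genes <- b2$genes[b2$genes$gene_id != "GA", , drop = FALSE]
  b2$transcripts <- b2$transcripts[b2$transcripts$gene_id != "GA", , drop = FALSE]
  b2$exons <- b2$exons[b2$exons$transcript_id %in% b2$transcripts$transcript_id, , drop = FALSE]
  expect_equal(nrow(find_biotype_flips(a, b2, c, "gene", "protein_coding")), 0L)
})

test_that("flip detection is symmetric in the outer releases and matches the oracle", {
  set.seed(9)
  for (i in 1:10) {
    out <- generate_random_series(random_release_script(seed = 300 + i))
    rel <- out$releases
    for (bt in c("protein_coding", "lincRNA", "miRNA")) {
      got <- find_biotype_flips(rel[[1]], rel[[2]], rel[[3]], "gene", bt)
      rev <- find_biotype_flips(rel[[3]], rel[[2]], rel[[1]], "gene", bt)
      expect_setequal(got$feature_id, rev$feature_id)
      expect_equal(sort(got$feature_id),
                   flip_oracle(rel[[1]], rel[[2]], rel[[3]], "gene", bt))
    }
  }
})

test_that("a two-way comparison degenerates to three regions", {
  a <- toy_release("a")
  b <- toy_release("b")
  b$genes <- rbind(b$genes, data.frame(
    gene_id = "GC", gene_name = "GAMMA", biotype = "lncRNA", chrom = "3",
    start = 1L, end = 100L, strand = "+", stringsAsFactors = FALSE))
  d <- three_way_compare(a, b, level = "gene")
  expect_named(d$counts, c("only_a", "only_b", "a_b"))
  expect_equal(d$regions$only_b, "GC")
  expect_equal(unname(d$counts["a_b"]), 2L)
})

test_that("write_diff emits the long region table and JSON counts", {
  a <- toy_release("a"); b <- toy_release("b")
  d <- three_way_compare(a, b, level = "gene")
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_diff(d, tsv, js)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 2L)  # both genes in the a_b region
  expect_equal(jsonlite::fromJSON(readLines(js))$a_b, 2L)
})
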