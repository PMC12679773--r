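#' Reference Venn-region enumeration for three identifier sets
#'
#' Assigns every identifier in the union of three sets to one of the seven
#' disjoint Venn regions by testing its membership in each set
#' individually. This per-identifier enumeration is deliberately written as
#' a direct loop over membership patterns, independent of the set-algebra
#' route used by [three_way_compare()], so the two can be checked against
#' each other.
#'
#' @param A,B,C character vectors of identifiers.
#' @return named list of identifier vectors with the same region names as
#'   [three_way_compare()].
#' @export
venn_enumerate <- function(A, B, C) {
  ids <- unique(c(A, B, C))
  pat <- paste0(as.integer(ids %in% A), as.integer(ids %in% B),
                as.integer(ids %in% C))
  key <- c("100" = "only_a", "010" = "only_b", "001" = "only_c",
           "110" = "a_b_not_c", "101" = "a_c_not_b", "011" = "b_c_not_a",
           "111" = "a_b_c")
  out <- stats::setNames(vector("list", length(key)), unname(key))
  for (k in names(key)) out[[key[[k]]]] <- ids[pat == k]
  out
}

#' Restrict a release to an allowed set of contigs
#'
#' Drops genes, transcripts, and exons on contigs outside the allowlist.
#' Filtering is idempotent and order-independent.
#'
#' @param release an [annotation_release()].
#' @param contig_allowlist character vector of contig names, or `"all"`.
#' @return a filtered [annotation_release()].
#' @export
filter_contigs <- function(release, contig_allowlist = primary_contigs()) {
  stopifnot(inherits(release, "annotation_release"))
  if (identical(contig_allowlist, "all")) return(release)
  g <- release$genes[release$genes$chrom %in% contig_allowlist, , drop = FALSE]
  tx <- release$transcripts[release$transcripts$chrom %in% contig_allowlist, , drop = FALSE]
  ex <- release$exons[release$exons$chrom %in% contig_allowlist, , drop = FALSE]
  annotation_release(release$label, g, tx, ex,
                     contig_policy = contig_allowlist,
                     provenance = release$provenance)
}

## ---- scripted release series -------------------------------------------

syn_gene_id <- function(i) sprintf("SYNG%05d", i)
syn_tx_id <- function(i) sprintf("SYNT%06d", i)

# Random exon chain: n_exons non-overlapping exons downstream of `origin`.
random_exons <- function(origin, n_exons) {
  starts <- ends <- integer(n_exons)
  pos <- origin
  for (j in seq_len(n_exons)) {
    pos <- pos + sample(50:500, 1L)
    w <- sample(80:600, 1L)
    starts[j] <- pos; ends[j] <- pos + w - 1L
    pos <- ends[j]
  }
  list(start = starts, end = ends)
}

#' Script for a synthetic multi-release annotation series
#'
#' Describes a base release plus a list of per-step edit events (gene and
#' transcript additions and drops, transient biotype flips), from which
#' [generate_release_series()] deterministically produces GTF files and
#' ground-truth tables. Identifiers are deterministic (`SYNG...`,
#' `SYNT...`) so events can reference them.
#'
#' @param n_genes number of primary-contig genes in the base release.
#' @param mean_isoforms mean isoform count per gene; counts are drawn as
#'   `1 + Geometric`, giving the long right tail real annotations show.
#' @param n_alt_contig_genes genes placed on an alternative contig
#'   (`HSCHR1_1_CTG3`) to exercise the contig filter; they are excluded
#'   from all truth tables.
#' @param events list of per-step event lists, each with optional elements
#'   `add_gene` (count), `drop_gene` (gene ids), `add_transcript` (gene
#'   ids, one new transcript each), `drop_transcript` (transcript ids) and
#'   `flip_biotype` (list of `list(id, level, to, revert)`); with
#'   `revert = TRUE` the original biotype is restored in the following
#'   step. The number of releases is `length(events) + 1`.
#' @param seed integer seed; the whole series is a deterministic function
#'   of the script.
#' @return object of class `release_script`.
#' @export
release_script <- function(n_genes = 40, mean_isoforms = 3,
                           n_alt_contig_genes = 2,
                           events = list(list(), list()), seed = 1L) {
  stopifnot(n_genes >= 1, mean_isoforms >= 1, length(events) >= 1)
  structure(list(n_genes = n_genes, mean_isoforms = mean_isoforms,
                 n_alt_contig_genes = n_alt_contig_genes,
                 events = events, seed = as.integer(seed)),
            class = "release_script")
}

# gene biotypes and, per gene biotype, candidate transcript biotypes
syn_gene_biotypes <- c(protein_coding = 0.45, lincRNA = 0.2,
                       processed_pseudogene = 0.15, miRNA = 0.1, TEC = 0.1)
syn_tx_biotypes <- function(gene_biotype) {
  if (gene_biotype == "protein_coding")
    c("protein_coding", "retained_intron", "nonsense_mediated_decay",
      "protein_coding_CDS_not_defined")
  else gene_biotype
}

# Build one gene (plus transcripts/exons) as a list of data.frame pieces.
build_gene <- function(gene_idx, tx_counter, chrom, mean_isoforms) {
  gid <- syn_gene_id(gene_idx)
  biotype <- sample(names(syn_gene_biotypes), 1L, prob = syn_gene_biotypes)
  strand <- sample(c("+", "-"), 1L)
  origin <- gene_idx * 100000L
  n_iso <- 1L + stats::rgeom(1L, prob = 1 / mean_isoforms)
  tx <- ex <- list()
  for (k in seq_len(n_iso)) {
    tid <- syn_tx_id(tx_counter + k)
    exch <- random_exons(origin, sample(1:5, 1L))
    tbio <- sample(syn_tx_biotypes(biotype), 1L)
    tx[[k]] <- data.frame(transcript_id = tid, gene_id = gid, biotype = tbio,
                          chrom = chrom, strand = strand,
                          length = sum(exch$end - exch$start + 1L),
                          n_exons = length(exch$start),
                          stringsAsFactors = FALSE)
    ex[[k]] <- data.frame(transcript_id = tid, chrom = chrom,
                          start = exch$start, end = exch$end, strand = strand,
                          stringsAsFactors = FALSE)
  }
  tx <- do.call(rbind, tx); ex <- do.call(rbind, ex)
  gene <- data.frame(gene_id = gid, gene_name = paste0("SYN-", gene_idx),
                     biotype = biotype, chrom = chrom,
                     start = min(ex$start), end = max(ex$end),
                     strand = strand, stringsAsFactors = FALSE)
  list(gene = gene, tx = tx, ex = ex, n_tx = nrow(tx))
}

apply_release_events <- function(rel, ev, counters, mean_isoforms, step) {
  g <- rel$genes; tx <- rel$transcripts; ex <- rel$exons
  flips_applied <- list()
  if (!is.null(ev$drop_gene)) {
    missing <- setdiff(ev$drop_gene, g$gene_id)
    if (length(missing))
      stop("step ", step, ": drop_gene references absent id(s): ",
           paste(missing, collapse = ", "))
    tx_drop <- tx$transcript_id[tx$gene_id %in% ev$drop_gene]
    g <- g[!g$gene_id %in% ev$drop_gene, , drop = FALSE]
    tx <- tx[!tx$gene_id %in% ev$drop_gene, , drop = FALSE]
    ex <- ex[!ex$transcript_id %in% tx_drop, , drop = FALSE]
  }
  if (!is.null(ev$drop_transcript)) {
    missing <- setdiff(ev$drop_transcript, tx$transcript_id)
    if (length(missing))
      stop("step ", step, ": drop_transcript references absent id(s): ",
           paste(missing, collapse = ", "))
    tx <- tx[!tx$transcript_id %in% ev$drop_transcript, , drop = FALSE]
    ex <- ex[!ex$transcript_id %in% ev$drop_transcript, , drop = FALSE]
  }
  if (!is.null(ev$add_gene) && ev$add_gene > 0) {
    for (i in seq_len(ev$add_gene)) {
      counters$gene <- counters$gene + 1L
      piece <- build_gene(counters$gene, counters$tx,
                          as.character(sample(1:22, 1L)), mean_isoforms)
      counters$tx <- counters$tx + piece$n_tx
      g <- rbind(g, piece$gene); tx <- rbind(tx, piece$tx)
      ex <- rbind(ex, piece$ex)
    }
  }
  if (!is.null(ev$add_transcript)) {
    for (gid in ev$add_transcript) {
      gi <- match(gid, g$gene_id)
      if (is.na(gi))
        stop("step ", step, ": add_transcript references absent gene: ", gid)
      counters$tx <- counters$tx + 1L
      tid <- syn_tx_id(counters$tx)
      exch <- random_exons(g$start[gi], sample(1:4, 1L))
      tx <- rbind(tx, data.frame(
        transcript_id = tid, gene_id = gid,
        biotype = sample(syn_tx_biotypes(g$biotype[gi]), 1L),
        chrom = g$chrom[gi], strand = g$strand[gi],
        length = sum(exch$end - exch$start + 1L),
        n_exons = length(exch$start), stringsAsFactors = FALSE))
      ex <- rbind(ex, data.frame(
        transcript_id = tid, chrom = g$chrom[gi], start = exch$start,
        end = exch$end, strand = g$strand[gi], stringsAsFactors = FALSE))
      g$end[gi] <- max(g$end[gi], max(exch$end))
    }
  }
  for (fl in ev$flip_biotype %||% list()) {
    if (fl$level == "gene") {
      i <- match(fl$id, g$gene_id)
      if (is.na(i)) stop("step ", step, ": flip references absent gene: ", fl$id)
      fl$from <- g$biotype[i]
      g$biotype[i] <- fl$to
    } else {
      i <- match(fl$id, tx$transcript_id)
      if (is.na(i))
        stop("step ", step, ": flip references absent transcript: ", fl$id)
      fl$from <- tx$biotype[i]
      tx$biotype[i] <- fl$to
    }
    flips_applied[[length(flips_applied) + 1L]] <- fl
  }
  list(release = annotation_release(paste0("release_", step + 1L), g, tx, ex,
                                    contig_policy = "all"),
       counters = counters, flips = flips_applied)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a scripted series of annotation releases
#'
#' Builds the base release from the script's seed, applies each step's edit
#' events in order, and (optionally) writes one Ensembl-dialect GTF per
#' release. Alongside the releases it returns ground-truth tables implied
#' by the events: for a three-release series, the seven Venn-region
#' memberships at gene and transcript level (computed by per-identifier
#' enumeration, see [venn_enumerate()]) and the list of scripted transient
#' biotype flips. Truth tables cover primary-contig features only, matching
#' what [parse_gtf()] keeps by default.
#'
#' @param script a [release_script()].
#' @param dir optional directory; when given, GTF files are written there
#'   and their paths returned.
#' @return list with `releases` (primary-contig [annotation_release()]
#'   objects), `full_releases` (including alternative-contig features, as
#'   written to GTF), `gtf_paths` (or `NULL`), and `truth` (list with
#'   `venn_gene`, `venn_transcript`, `flips`).
#' @export
generate_release_series <- function(script, dir = NULL) {
  stopifnot(inherits(script, "release_script"))
  set.seed(script$seed)
  counters <- list(gene = 0L, tx = 0L)
  g <- tx <- ex <- list()
  for (i in seq_len(script$n_genes)) {
    counters$gene <- counters$gene + 1L
    piece <- build_gene(counters$gene, counters$tx,
                        as.character(sample(1:22, 1L)), script$mean_isoforms)
    counters$tx <- counters$tx + piece$n_tx
    g[[i]] <- piece$gene; tx[[i]] <- piece$tx; ex[[i]] <- piece$ex
  }
  for (i in seq_len(script$n_alt_contig_genes)) {
    counters$gene <- counters$gene + 1L
    piece <- build_gene(counters$gene, counters$tx, "HSCHR1_1_CTG3",
                        script$mean_isoforms)
    counters$tx <- counters$tx + piece$n_tx
    g[[length(g) + 1L]] <- piece$gene
    tx[[length(tx) + 1L]] <- piece$tx
    ex[[length(ex) + 1L]] <- piece$ex
  }
  base <- annotation_release("release_1", do.call(rbind, g),
                             do.call(rbind, tx), do.call(rbind, ex),
                             contig_policy = "all")
  full <- list(base)
  scripted_flips <- list()
  pending_revert <- list()
  for (s in seq_along(script$events)) {
    ev <- script$events[[s]]
    # reverts scheduled by the previous step's flips run first
    if (length(pending_revert)) {
      ev$flip_biotype <- c(pending_revert, ev$flip_biotype %||% list())
      pending_revert <- list()
    }
    step <- apply_release_events(full[[s]], ev, counters,
                                 script$mean_isoforms, s)
    counters <- step$counters
    full[[s + 1L]] <- step$release
    for (fl in step$flips) {
      if (isTRUE(fl$revert)) {
        pending_revert[[length(pending_revert) + 1L]] <-
          list(id = fl$id, level = fl$level, to = fl$from, revert = FALSE)
        scripted_flips[[length(scripted_flips) + 1L]] <-
          list(id = fl$id, level = fl$level, from = fl$from, to = fl$to,
               flipped_at = s + 1L)
      }
    }
  }
  if (length(pending_revert))
    stop("a flip with revert = TRUE was scripted at the final step; ",
         "there is no later release to revert in")
  primary <- lapply(full, filter_contigs)
  truth <- list(flips = scripted_flips)
  if (length(primary) == 3L) {
    truth$venn_gene <- venn_enumerate(id_set(primary[[1L]], "gene"),
                                      id_set(primary[[2L]], "gene"),
                                      id_set(primary[[3L]], "gene"))
    truth$venn_transcript <- venn_enumerate(
      id_set(primary[[1L]], "transcript"),
      id_set(primary[[2L]], "transcript"),
      id_set(primary[[3L]], "transcript"))
  }
  gtf_paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gtf_paths <- vapply(full, function(r)
      write_gtf(r, file.path(dir, paste0(r$label, ".gtf")),
                source_label = "synthetic"), character(1L))
  }
  list(releases = primary, full_releases = full, gtf_paths = gtf_paths,
       truth = truth, script = script)
}

#' Default demonstration script: a three-release series with every event type
#'
#' A 40-gene base release followed by two edit steps exercising gene and
#' transcript additions, drops, and one reverting biotype flip — the
#' canonical fixture for whole-pipeline recovery checks.
#'
#' @param seed integer seed.
#' @return a [release_script()] with concrete event identifiers resolved
#'   against the base release this seed produces.
#' @export
default_release_script <- function(seed = 1L) {
  base <- generate_release_series(
    release_script(n_genes = 40, mean_isoforms = 3, n_alt_contig_genes = 2,
                   events = list(list(), list()), seed = seed))$releases[[1L]]
  tx_of <- function(gid) base$transcripts$transcript_id[
    base$transcripts$gene_id == gid]
  untouched <- setdiff(base$genes$gene_id,
                       c("SYNG00005", "SYNG00009", "SYNG00012", "SYNG00020"))
  rich <- untouched[vapply(untouched, function(g) length(tx_of(g)),
                           integer(1L)) >= 3L]
  release_script(
    n_genes = 40, mean_isoforms = 3, n_alt_contig_genes = 2,
    events = list(
      list(add_gene = 3,
           drop_gene = c("SYNG00005", "SYNG00012"),
           drop_transcript = tx_of(rich[1L])[1L],
           add_transcript = c("SYNG00002", "SYNG00002", "SYNG00007"),
           flip_biotype = list(list(
             id = "SYNG00009", level = "gene",
             to = "transcribed_unprocessed_pseudogene", revert = TRUE))),
      list(add_gene = 2,
           drop_gene = "SYNG00020",
           drop_transcript = tx_of(rich[2L])[1:2])),
    seed = seed)
}

#' Random edit script for a three-release series
#'
#' Draws random add/drop/flip events for two steps, giving a three-release
#' series with nontrivial Venn regions and (with probability controlled by
#' `flip_prob`) a scripted transient biotype flip. Used for randomized
#' oracle-equivalence testing.
#'
#' @param seed integer seed.
#' @param n_genes base-release size.
#' @return a [release_script()].
#' @export
random_release_script <- function(seed, n_genes = 12) {
  set.seed(seed)
  mk_step <- function() {
    list(add_gene = sample(0:3, 1L),
         drop_gene = NULL,   # ids filled in at generation time via drops below
         n_drop_gene = sample(0:2, 1L),
         n_drop_transcript = sample(0:2, 1L),
         do_flip = stats::runif(1) < 0.5)
  }
  structure(list(n_genes = n_genes, mean_isoforms = 2,
                 n_alt_contig_genes = 1L,
                 steps = list(mk_step(), mk_step()), seed = as.integer(seed)),
            class = "random_release_plan")
}

#' Materialize a random three-release series
#'
#' Resolves the abstract random plan of [random_release_script()] into
#' concrete drop/flip events against the base release produced by its seed,
#' then runs [generate_release_series()].
#'
#' @param plan a plan from [random_release_script()].
#' @return as [generate_release_series()].
#' @export
generate_random_series <- function(plan) {
  stopifnot(inherits(plan, "random_release_plan"))
  set.seed(plan$seed + 1000L)
  probe <- generate_release_series(
    release_script(n_genes = plan$n_genes, mean_isoforms = plan$mean_isoforms,
                   n_alt_contig_genes = plan$n_alt_contig_genes,
                   events = list(list(), list()), seed = plan$seed))
  base <- probe$releases[[1L]]
  events <- list()
  avail_g <- base$genes$gene_id
  avail_t <- base$transcripts$transcript_id
  protected <- character(0)  # flipped genes must survive until the revert
  for (s in 1:2) {
    st <- plan$steps[[s]]
    cand_g <- setdiff(avail_g, protected)
    drop_g <- if (st$n_drop_gene && length(cand_g))
      sample(cand_g, min(st$n_drop_gene, length(cand_g))) else NULL
    avail_g <- setdiff(avail_g, drop_g)
    cand_t <- setdiff(avail_t,
                      base$transcripts$transcript_id[base$transcripts$gene_id %in% drop_g])
    drop_t <- if (st$n_drop_transcript) sample(cand_t, min(st$n_drop_transcript, length(cand_t))) else NULL
    avail_t <- setdiff(cand_t, drop_t)
    flip <- NULL
    if (st$do_flip && s == 1L && length(avail_g)) {
      fid <- sample(avail_g, 1L)
      protected <- c(protected, fid)
      flip <- list(list(id = fid, level = "gene",
                        to = "transcribed_unprocessed_pseudogene",
                        revert = TRUE))
    }
    events[[s]] <- list(add_gene = st$add_gene, drop_gene = drop_g,
                        drop_transcript = drop_t, flip_biotype = flip)
  }
  generate_release_series(
    release_script(n_genes = plan$n_genes, mean_isoforms = plan$mean_isoforms,
                   n_alt_contig_genes = plan$n_alt_contig_genes,
                   events = events, seed = plan$seed))
}

## ---- scripted counts matrices ------------------------------------------

#' Script for a synthetic counts matrix with planted truth
#'
#' Describes tissues and samples, expression tiers, overdispersion, and
#' planted structures: which transcripts are expressed in which tissues,
#' boundary transcripts pinned at the filter threshold, high-count
#' background transcripts that stabilize library sizes, and abundance genes
#' with fixed new-to-old count ratios. Defaults mirror the structure of a
#' nine-tissue, 58-sample long-read cohort with multi-million-read
#' libraries.
#'
#' @param tissues named integer vector: samples per tissue.
#' @param n_genes regular (non-background, non-abundance) genes.
#' @param isoforms_per_gene isoforms per regular gene.
#' @param new_isoform_fraction probability a regular isoform is flagged as
#'   newly annotated.
#' @param expressed_prob per tissue, probability a regular isoform is
#'   planted as expressed there.
#' @param mean_expressed,mean_silent negative-binomial means for the
#'   expressed and silent tiers (unique read counts).
#' @param dispersion negative-binomial size parameter; smaller is more
#'   overdispersed.
#' @param n_background background transcripts per sample with
#'   `background_mean` counts each, dominating the library size.
#' @param background_mean mean counts of a background transcript.
#' @param n_boundary transcripts pinned at exactly 1 count in every sample;
#'   they must always fail the strict median-count rule.
#' @param abundance_ratios named numeric vector: one planted gene per
#'   entry, value = the new-isoform share of the gene's counts (constant
#'   across samples).
#' @param abundance_scale total counts per abundance gene per sample.
#' @param clamp logical; `TRUE` (default) enforces the planted truth
#'   exactly after sampling, `FALSE` leaves raw negative-binomial draws.
#' @param seed integer seed for the count draws.
#' @param design_seed integer seed for the planted design (which isoforms
#'   are new, where they are expressed). Kept separate from `seed` so that
#'   changing the count seed never changes the truth tables.
#' @return object of class `counts_script`.
#' @export
counts_script <- function(tissues = c(cerebellar_hemisphere = 7L,
                                      frontal_cortex = 7L, putamen = 6L,
                                      liver = 6L, lung = 6L,
                                      skeletal_muscle = 7L,
                                      heart_atrial_appendage = 6L,
                                      heart_left_ventricle = 6L,
                                      cultured_fibroblasts = 7L),
                          n_genes = 30L, isoforms_per_gene = 3L,
                          new_isoform_fraction = 0.3, expressed_prob = 0.4,
                          mean_expressed = 50, mean_silent = 0.3,
                          dispersion = 2, n_background = 20L,
                          background_mean = 1e5, n_boundary = 6L,
                          abundance_ratios = c(ABG01 = 0.75, ABG02 = 0.5,
                                               ABG03 = 1.0, ABG04 = 0.25),
                          abundance_scale = 400L, clamp = TRUE, seed = 1L,
                          design_seed = 19L) {
  stopifnot(length(tissues) >= 1, all(tissues >= 1),
            all(abundance_ratios >= 0), all(abundance_ratios <= 1))
  structure(list(tissues = tissues, n_genes = n_genes,
                 isoforms_per_gene = isoforms_per_gene,
                 new_isoform_fraction = new_isoform_fraction,
                 expressed_prob = expressed_prob,
                 mean_expressed = mean_expressed, mean_silent = mean_silent,
                 dispersion = dispersion, n_background = n_background,
                 background_mean = background_mean, n_boundary = n_boundary,
                 abundance_ratios = abundance_ratios,
                 abundance_scale = abundance_scale, clamp = clamp,
                 seed = as.integer(seed),
                 design_seed = as.integer(design_seed)),
            class = "counts_script")
}

#' Generate a counts matrix with planted ground truth
#'
#' Draws overdispersed unique-read counts from a negative-binomial model
#' and, in clamped mode, post-hoc enforces every planted fact so recovery
#' tests are exact: expressed transcripts end with per-sample counts of at
#' least 2 and at least one count per million reads of their library,
#' silent and boundary transcripts are capped at 1 count, and abundance
#' genes carry exact fixed new-to-old ratios. Changing the seed changes the
#' counts but never the clamped truth tables.
#'
#' @param script a [counts_script()].
#' @return list with `cm` (a [counts_matrix()] with `gene_of` set),
#'   `new_ids` (planted newly annotated transcripts), `truth` (list:
#'   `expressed` per-tissue identifier vectors, `abundance` data.frame of
#'   gene x tissue planted shares), and `plan` (per-transcript metadata).
#' @export
generate_counts <- function(script) {
  stopifnot(inherits(script, "counts_script"))
  set.seed(script$design_seed)  # plan first; count draws re-seed below
  tissues <- script$tissues
  sample_ids <- unlist(lapply(names(tissues), function(t)
    paste0(t, "_s", seq_len(tissues[[t]]))))
  tissue_of <- stats::setNames(
    rep(names(tissues), times = unname(tissues)), sample_ids)
  n_smp <- length(sample_ids)

  # --- transcript plan ----------------------------------------------------
  reg_gene <- sprintf("SYNG%05d", seq_len(script$n_genes))
  reg_tx <- character(0); reg_tx_gene <- character(0)
  for (i in seq_len(script$n_genes)) {
    k <- script$isoforms_per_gene
    reg_tx <- c(reg_tx, sprintf("SYNT%05d_%d", i, seq_len(k)))
    reg_tx_gene <- c(reg_tx_gene, rep(reg_gene[i], k))
  }
  is_new_reg <- stats::runif(length(reg_tx)) < script$new_isoform_fraction
  bg_tx <- sprintf("BGT%03d", seq_len(script$n_background))
  bg_gene <- sprintf("BGG%03d", seq_len(script$n_background))
  bd_tx <- sprintf("BDT%03d", seq_len(script$n_boundary))
  bd_gene <- sprintf("BDG%03d", seq_len(script$n_boundary))
  ab_genes <- names(script$abundance_ratios)
  ab_tx <- ab_tx_gene <- character(0); ab_is_new <- logical(0)
  for (g in ab_genes) {
    ab_tx <- c(ab_tx, paste0(g, "_new1"), paste0(g, "_new2"),
               paste0(g, "_old1"), paste0(g, "_old2"))
    ab_tx_gene <- c(ab_tx_gene, rep(g, 4L))
    ab_is_new <- c(ab_is_new, TRUE, TRUE, FALSE, FALSE)
  }
  tx_ids <- c(reg_tx, bg_tx, bd_tx, ab_tx)
  gene_of <- stats::setNames(c(reg_tx_gene, bg_gene, bd_gene, ab_tx_gene),
                             tx_ids)
  is_new <- stats::setNames(
    c(is_new_reg, rep(FALSE, length(bg_tx)),
      rep(TRUE, length(bd_tx)),  # boundary rows probe the new-isoform filter
      ab_is_new), tx_ids)

  # planted expressed design: regular transcripts per tissue, Bernoulli
  expressed_plan <- matrix(FALSE, length(tx_ids), length(tissues),
                           dimnames = list(tx_ids, names(tissues)))
  expressed_plan[reg_tx, ] <-
    stats::runif(length(reg_tx) * length(tissues)) < script$expressed_prob
  expressed_plan[bg_tx, ] <- TRUE
  # abundance isoforms: expressed wherever their fixed count is nonzero
  ab_count <- stats::setNames(numeric(length(ab_tx)), ab_tx)
  for (g in ab_genes) {
    r <- script$abundance_ratios[[g]]
    ab_count[paste0(g, c("_new1", "_new2"))] <- r * script$abundance_scale / 2
    ab_count[paste0(g, c("_old1", "_old2"))] <- (1 - r) * script$abundance_scale / 2
  }
  expressed_plan[ab_tx, ] <- matrix(rep(ab_count > 0, length(tissues)),
                                    ncol = length(tissues))

  # --- draw counts --------------------------------------------------------
  set.seed(script$seed)
  mu <- matrix(script$mean_silent, length(tx_ids), n_smp,
               dimnames = list(tx_ids, sample_ids))
  for (t in names(tissues)) {
    smp <- sample_ids[tissue_of == t]
    on <- rownames(expressed_plan)[expressed_plan[, t]]
    mu[on, smp] <- script$mean_expressed
  }
  mu[bg_tx, ] <- script$background_mean
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = script$dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  counts[ab_tx, ] <- matrix(rep(ab_count, n_smp), ncol = n_smp)

  if (script$clamp) {
    off_rows <- !expressed_plan  # tx x tissue
    for (t in names(tissues)) {
      smp <- sample_ids[tissue_of == t]
      off <- setdiff(rownames(counts)[off_rows[, t]], ab_tx)
      counts[off, smp] <- pmin(counts[off, smp], 1)
    }
    counts[bd_tx, ] <- 1
    # raise expressed rows until both the count rule and CPM >= 1 hold;
    # raising counts grows libraries far slower than the threshold, so a
    # few passes reach a fixed point
    for (pass in 1:10) {
      lib <- colSums(counts)
      need <- pmax(ceiling(lib / 1e6), 2)
      changed <- FALSE
      for (t in names(tissues)) {
        smp <- sample_ids[tissue_of == t]
        on <- setdiff(rownames(counts)[expressed_plan[, t]], ab_tx)
        for (s in smp) {
          low <- counts[on, s] < need[[s]]
          if (any(low)) {
            counts[on[low], s] <- need[[s]]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }

  cm <- counts_matrix(counts, tissue_of, gene_of = gene_of)
  truth_expr <- lapply(names(tissues), function(t)
    sort(rownames(expressed_plan)[expressed_plan[, t]]))
  names(truth_expr) <- names(tissues)
  truth_ab <- do.call(rbind, lapply(ab_genes, function(g)
    data.frame(gene_id = g, tissue = names(tissues),
               abundance = unname(script$abundance_ratios[[g]]),
               stringsAsFactors = FALSE)))
  list(cm = cm,
       new_ids = names(is_new)[is_new],
       truth = list(expressed = truth_expr, abundance = truth_ab),
       plan = list(gene_of = gene_of, is_new = is_new,
                   expressed_plan = expressed_plan,
                   background = bg_tx, boundary = bd_tx,
                   abundance_transcripts = ab_tx))
}
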