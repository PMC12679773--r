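# Independent brute-force oracles. These deliberately use a different
# computational route than the package functions they are checked against.

# transcript length by literally counting covered bases one by one
per_base_length_oracle <- function(exons) {
  covered <- unlist(lapply(seq_len(nrow(exons)),
                           function(i) seq(exons$start[i], exons$end[i])))
  length(covered)
}

# N50 by testing every candidate length: the largest member length L such
# that members of length >= L hold at least half of all bases
n50_candidate_oracle <- function(lengths) {
  total <- sum(as.numeric(lengths))
  ok <- vapply(unique(lengths),
               function(L) sum(as.numeric(lengths[lengths >= L])) >= total / 2,
               logical(1))
  max(unique(lengths)[ok])
}

# same exhaustive-candidate test, evaluated for all candidates at once via
# ascending sort and suffix totals; O(n log n), usable on large cohorts
n50_suffix_oracle <- function(lengths) {
  s <- sort(lengths)
  suffix <- rev(cumsum(rev(as.numeric(s))))  # bases in members >= s[i] ... almost:
  # ties: suffix at the FIRST occurrence of a value covers all members >= it
  first <- !duplicated(s)
  cand <- s[first]
  tot_ge <- suffix[first]
  max(cand[tot_ge >= sum(as.numeric(s)) / 2])
}

# biotype flips by direct per-identifier comparison of the three releases
flip_oracle <- function(a, b, c, level, biotype) {
  bio_of <- function(rel) {
    tab <- if (level == "gene") rel$genes else rel$transcripts
    key <- if (level == "gene") tab$gene_id else tab$transcript_id
    stats::setNames(tab$biotype, key)
  }
  ba <- bio_of(a); bb <- bio_of(b); bc <- bio_of(c)
  shared <- intersect(intersect(names(ba), names(bb)), names(bc))
  sort(shared[!is.na(ba[shared]) & ba[shared] == biotype &
                bc[shared] == biotype & bb[shared] != biotype])
}
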