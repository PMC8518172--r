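# Hand-built fixtures and independent oracles shared across test files.
# Everything is constructed in code; no data files.

# Three genes with disjoint blocks: A (2 isoforms sharing a core), B and C
# (single isoform each). Useful for removal-law and summarization tests.
toy_annotation <- function() {
  tx <- data.frame(
    transcript_id = c("A1", "A2", "B1", "C1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    family_id = c("gA", "gA", "gB", "gC"),
    length = c(300L, 200L, 400L, 250L))
  tx$blocks <- list(c("a_core", "a_ext"), "a_core", "b1", "c1")
  bl <- data.frame(block_id = c("a_core", "a_ext", "b1", "c1"),
                   length = c(200L, 100L, 400L, 250L), pad = FALSE)
  annotation(tx, bl, label = "toy")
}

# Two single-isoform paralogs of equal length sharing a stated fraction of
# their block length.
two_paralog_annotation <- function(shared_frac = 0.5, len = 1000L) {
  sh <- as.integer(round(shared_frac * len))
  pr <- len - sh
  tx <- data.frame(
    transcript_id = c("P1", "P2"), gene_id = c("g1", "g2"),
    family_id = c("fam", "fam"), length = c(len, len))
  tx$blocks <- list(c("shared", "p1"), c("shared", "p2"))
  bl <- data.frame(block_id = c("shared", "p1", "p2"),
                   length = c(sh, pr, pr), pad = FALSE)
  annotation(tx, bl, label = "paralog_pair")
}

# Fixture for the competitor-removal inflation mechanism: a low-expression
# target gene whose only transcript shares block S1 with one isoform of a
# highly expressed 6-isoform competitor paralog, on a background of
# single-isoform genes spanning ~3.5 decades of expression.
competitor_fixture <- function(n_background = 80L, seed = 7L) {
  bg_id <- sprintf("BG%02d", seq_len(n_background))
  tx <- data.frame(
    transcript_id = c("tgt_T1", sprintf("cmp_T%d", 1:6),
                      paste0(bg_id, "_T1")),
    gene_id = c("tgt", rep("cmp", 6), bg_id),
    family_id = c("famTC", rep("famTC", 6), bg_id),
    length = c(1000L, rep(0L, 6), rep(1000L, n_background)))
  cmp_blocks <- c(list(c("cmp_core", "S1")),
                  lapply(1:5, function(i) c("cmp_core", sprintf("cmp_p%d", i))))
  tx$blocks <- c(list(c("S1", "tgt_p")), cmp_blocks,
                 lapply(bg_id, function(g) paste0(g, "_b")))
  bl <- data.frame(
    block_id = c("S1", "tgt_p", "cmp_core", sprintf("cmp_p%d", 1:5),
                 paste0(bg_id, "_b")),
    length = c(300L, 700L, 400L, rep(600L, 5), rep(1000L, n_background)),
    pad = FALSE)
  blen <- setNames(bl$length, bl$block_id)
  tx$length <- vapply(tx$blocks, function(b) sum(blen[b]), numeric(1))
  ann <- annotation(tx, bl, label = "competitor_fixture")
  w <- withr::with_seed(seed, {
    bg_w <- 10^runif(n_background, 0.5, 4)
    cmp_w <- rep(10^3.5 / 6, 6)          # high expression, even isoform split
    c(10^0.2, cmp_w, bg_w)               # target is near the expression floor
  })
  truth <- expression_truth(setNames(w / sum(w), tx$transcript_id))
  profile <- species_profile(
    "preclin",
    setNames(rep(1L, 2 + n_background), c("tgt", "cmp", bg_id)),
    ortholog_genes = c("tgt", "cmp", bg_id), reference = ann)
  list(ann = ann, truth = truth, profile = profile)
}

# Observed-data log-likelihood of a block-level read configuration: each
# "site" is a block with count n and a member transcript set; a read from
# transcript t covers block b with probability theta_t * l_b / sum(theta l).
block_loglik <- function(theta, lens, site_members, site_blen, site_counts) {
  denom <- sum(theta * lens)
  ll <- 0
  for (i in seq_along(site_members)) {
    p <- sum(theta[site_members[[i]]]) * site_blen[i] / denom
    ll <- ll + site_counts[i] * log(p)
  }
  ll
}

# Exhaustive grid maximum likelihood over the simplex (2 or 3 transcripts).
grid_ml <- function(lens, site_members, site_blen, site_counts,
                    step = 0.002) {
  k <- length(lens)
  best <- -Inf; best_theta <- rep(1 / k, k)
  if (k == 2L) {
    for (a in seq(step, 1 - step, by = step)) {
      th <- c(a, 1 - a)
      ll <- block_loglik(th, lens, site_members, site_blen, site_counts)
      if (ll > best) { best <- ll; best_theta <- th }
    }
  } else if (k == 3L) {
    for (a in seq(step, 1 - 2 * step, by = step)) {
      for (b in seq(step, 1 - a - step, by = step)) {
        th <- c(a, b, 1 - a - b)
        ll <- block_loglik(th, lens, site_members, site_blen, site_counts)
        if (ll > best) { best <- ll; best_theta <- th }
      }
    }
  } else stop("grid_ml supports 2 or 3 transcripts")
  list(loglik = best, theta = best_theta)
}

# Forge-and-quantify bundle at a configurable scale; used by several files.
desk_pipeline <- function(n_genes = 200L, n_reads = 2e4, seed = 1L) {
  ann <- forge_transcriptome(n_genes, seed = seed)
  truth <- simulate_expression(ann, seed = seed + 1L)
  reads <- simulate_reads(truth, ann, n_reads, seed = seed + 2L)
  fq <- quantify_sample(reads, ann)
  fg <- summarize_to_gene(fq, ann, ann)
  list(ann = ann, truth = truth, reads = reads, fq = fq, fg = fg)
}
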