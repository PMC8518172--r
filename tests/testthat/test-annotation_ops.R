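# 105 single-transcript genes with disjoint blocks: a clean sampling pool.
flat_annotation <- function(n = 105L) {
  ids <- sprintf("T%03d", seq_len(n))
  tx <- data.frame(transcript_id = ids, gene_id = sprintf("g%03d", seq_len(n)),
                   family_id = sprintf("g%03d", seq_len(n)),
                   length = rep(500L, n))
  tx$blocks <- as.list(paste0("b", seq_len(n)))
  bl <- data.frame(block_id = paste0("b", seq_len(n)), length = 500L,
                   pad = FALSE)
  annotation(tx, bl, label = "flat")
}

test_that("subsample_sweep honors the keep-set protocol and counts", {
  full <- flat_annotation()
  keep <- sprintf("T%03d", 1:5)
  sch <- sweep_scheme(fractions = c(10, 50, 99), reps_per_fraction = 4,
                      keep_set = keep, seed = 3)
  anns <- subsample_sweep(full, sch)
  man <- attr(anns, "manifest")
  expect_equal(length(anns), 12L)
  expect_false(anyDuplicated(man$label) > 0)
  for (a in anns) {
    expect_true(all(keep %in% tx_ids(a)))
    expect_false(anyDuplicated(tx_ids(a)) > 0)
  }
  # pool is 100 after keep-set removal: 99% -> 99 sampled + 5 controls
  n99 <- vapply(anns[man$fraction == 99], function(a) length(tx_ids(a)),
                integer(1))
  expect_true(all(n99 == 104L))
  expect_true(all(vapply(anns[man$fraction == 10],
                         function(a) length(tx_ids(a)), integer(1)) == 15L))
  # determinism
  expect_identical(names(subsample_sweep(full, sch)), names(anns))
  expect_identical(tx_ids(subsample_sweep(full, sch)[[7]]), tx_ids(anns[[7]]))
  expect_error(subsample_sweep(full, sweep_scheme(keep_set = "nope")),
               class = "tpmdepth_input_error")
  expect_error(sweep_scheme(fractions = c(0, 50)),
               class = "tpmdepth_config_error")
})

test_that("remove_paralogs removes cross-gene family competitors only", {
  ann <- forge_transcriptome(80, seed = 14)
  tx <- ann$transcripts
  multi <- unique(tx$family_id[ave(tx$gene_id, tx$family_id,
                                   FUN = function(g) length(unique(g))) > 1])
  expect_gt(length(multi), 0)
  target <- unique(tx$gene_id[tx$family_id == multi[1]])[1]
  out <- remove_paralogs(ann, target)
  otx <- out$transcripts
  # target's transcripts intact
  expect_setequal(otx$transcript_id[otx$gene_id == target],
                  tx$transcript_id[tx$gene_id == target])
  # competitors gone
  expect_false(any(otx$family_id == multi[1] & otx$gene_id != target))
  # singleton-family target is an identity operation
  singleton <- unique(tx$gene_id[!tx$family_id %in% multi])[1]
  expect_setequal(tx_ids(remove_paralogs(ann, singleton)), tx_ids(ann))
  expect_error(remove_paralogs(ann, "no_such_gene"),
               class = "tpmdepth_input_error")
})

test_that("paralog removal reduces tpm multi-modality on a 2-family fixture", {
  fx <- competitor_fixture(n_background = 20L, seed = 5)
  rs <- simulate_reads(fx$truth, fx$ann, 3e4, seed = 6)
  # sweep in which the competitor isoform cmp_T1 is sometimes absent
  pool_sch <- sweep_scheme(fractions = 70, reps_per_fraction = 40,
                           keep_set = "tgt_T1", seed = 7)
  tgt_tpm <- function(base) {
    anns <- subsample_sweep(base, pool_sch)
    vapply(anns, function(a) {
      q <- quantify_sample(rs, a)
      q$tpm[q$transcript_id == "tgt_T1"]
    }, numeric(1))
  }
  bimodality <- function(x) {
    n <- length(x); m <- mean(x); s <- sd(x)
    g1 <- mean(((x - m) / s)^3)
    g2 <- mean(((x - m) / s)^4) - 3
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }
  before <- tgt_tpm(fx$ann)
  after <- tgt_tpm(remove_paralogs(fx$ann, "tgt"))
  expect_lte(bimodality(after), bimodality(before) + 1e-9)
})

test_that("preclinicalize emits exact per-gene counts over ortholog genes", {
  ann <- forge_transcriptome(60, seed = 9)
  prof <- forge_species_profile(ann, "dog", 2.5, ortholog_fraction = 0.7,
                                seed = 10)
  pc <- preclinicalize(ann, prof, reps = 8, seed = 11)
  expect_equal(length(pc$reduced), 8L)
  expect_setequal(gene_ids(pc$ortholog_full), prof$ortholog_genes)
  full_cnt <- n_transcripts_per_gene(pc$ortholog_full)
  for (a in pc$reduced) {
    # gene set preserved exactly
    expect_setequal(gene_ids(a), gene_ids(pc$ortholog_full))
    cnt <- n_transcripts_per_gene(a)
    want <- pmin(full_cnt[names(cnt)],
                 prof$per_gene_transcript_count[names(cnt)])
    expect_equal(cnt, want)
    expect_true(all(tx_ids(a) %in% tx_ids(pc$ortholog_full)))
  }
  # a gene whose profile count equals its full count is identical everywhere
  same <- names(full_cnt)[prof$per_gene_transcript_count[names(full_cnt)] ==
                            full_cnt]
  if (length(same)) {
    g <- same[1]
    ref <- sort(pc$ortholog_full$transcripts$transcript_id[
      pc$ortholog_full$transcripts$gene_id == g])
    for (a in pc$reduced)
      expect_identical(sort(a$transcripts$transcript_id[
        a$transcripts$gene_id == g]), ref)
  }
  # over-demanding profile errors
  bad <- species_profile("bad", setNames(99L, gene_ids(ann)[1]),
                         gene_ids(ann)[1])
  expect_error(preclinicalize(ann, bad, reps = 1),
               class = "tpmdepth_input_error")
})

test_that("vary_gene_lengths: padding halves the rate, never adds reads", {
  ann <- toy_annotation()
  expect_identical(
    tx_ids(vary_gene_lengths(ann, c(gB = 1), mode = "padded")), tx_ids(ann))

  tr <- expression_truth(setNames(c(0.3, 0.2, 0.3, 0.2),
                                  c("A1", "A2", "B1", "C1")))
  rs <- simulate_reads(tr, ann, 5000, seed = 15)
  padded <- vary_gene_lengths(ann, c(gB = 2), mode = "padded")
  expect_equal(padded$transcripts$length[padded$transcripts$transcript_id == "B1"],
               800L)
  q0 <- quantify_sample(rs, ann)
  q1 <- quantify_sample(rs, padded)
  m <- match(q1$transcript_id, q0$transcript_id)
  # counts can only be preserved or lost (up to EM convergence jitter)
  expect_true(all(q1$reads <= q0$reads[m] + 1e-3))
  # closed form: rate of B1 halves, denominator adjusts
  rate0 <- q0$reads / q0$length
  rate1 <- rate0; rate1[q0$transcript_id == "B1"] <- rate0[q0$transcript_id == "B1"] / 2
  expect_equal(q1$tpm, 1e6 * rate1[m] / sum(rate1), tolerance = 1e-6)

  trimmed <- vary_gene_lengths(ann, c(gA = 0.7), mode = "trimmed")
  expect_true(all(trimmed$transcripts$length >= 1))
  expect_error(vary_gene_lengths(ann, c(gA = -1)),
               class = "tpmdepth_input_error")
  expect_error(vary_gene_lengths(ann, c(zz = 2)),
               class = "tpmdepth_input_error")
})
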