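test_that("compute_tpm implements the printed arithmetic exactly", {
  expect_equal(compute_tpm(10, 100)$tpm, 1e6)
  expect_equal(compute_tpm(c(10, 30), c(100, 100))$tpm, c(250000, 750000))
  q <- compute_tpm(c(5, 5), c(100, 200))
  expect_equal(quant_S(q), 0.075)
  expect_equal(q$tpm, c(2e6 / 3, 1e6 / 3))
  expect_equal(sum(q$tpm), 1e6, tolerance = 1e-9)
  expect_error(compute_tpm(c(0, 0), c(10, 10)), class = "tpmdepth_input_error")
  expect_error(compute_tpm(c(1, 1), c(10, 0)), class = "tpmdepth_input_error")
})

test_that("assign_reads: unique tallies, unmapped exclusion, EM ties", {
  ann <- toy_annotation()
  rd <- read_set(origin = c("B1", "B1", "C1"), block = c("b1", "b1", "c1"))
  x <- assign_reads(rd, ann)
  expect_equal(unname(x[c("B1", "C1")]), c(2, 1))
  expect_equal(sum(x), 3)

  # dropping a transcript makes its uniquely-compatible reads unmapped
  sub <- tpmdepth:::subset_annotation(ann, c("A1", "A2", "B1"))
  x2 <- assign_reads(rd, sub)
  expect_equal(sum(x2), 2)
  expect_equal(attr(x2, "n_unmapped"), 1L)

  # fully symmetric transcripts (equal length, same sites) share equally
  par <- two_paralog_annotation(shared_frac = 0.5)
  rd3 <- read_set(origin = rep("P1", 4), block = rep("shared", 4))
  x3 <- assign_reads(rd3, par)
  expect_equal(unname(x3["P1"]), unname(x3["P2"]))
  expect_equal(sum(x3), 4)
})

test_that("EM matches the brute-force ML split on the 6/2/8 instance", {
  ann <- two_paralog_annotation(shared_frac = 0.5, len = 300L)
  rd <- read_set(origin = c(rep("P1", 6), rep("P2", 2), rep("P1", 8)),
                 block = c(rep("p1", 6), rep("p2", 2), rep("shared", 8)))
  x <- assign_reads(rd, ann)
  # analytic ML for equal lengths: theta_1 = 6/8, ambiguous split 6:2
  expect_equal(unname(x[c("P1", "P2")]), c(12, 4), tolerance = 1e-6)
})

test_that("EM attains the exhaustive grid ML on small random instances", {
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    lens <- sample(100:500, k)
    ids <- LETTERS[1:k]
    # random site structure: singleton blocks + random multi-member blocks
    members <- c(lapply(1:k, identity),
                 replicate(sample(1:3, 1),
                           sort(sample(1:k, sample(2:k, 1))),
                           simplify = FALSE))
    members <- unique(members)
    blen <- rep(50L, length(members))
    counts <- sample(0:8, length(members), replace = TRUE)
    if (sum(counts) == 0 || sum(counts) > 20) next
    keep <- counts > 0
    site_members <- members[keep]; site_counts <- counts[keep]
    site_blen <- blen[keep]
    if (length(site_members) == 0) next

    tx <- data.frame(transcript_id = ids, gene_id = ids,
                     family_id = rep("F", k), length = lens)
    # per-transcript blocks: its singleton site plus shared sites
    tx$blocks <- lapply(1:k, function(t)
      c(sprintf("s%d", which(vapply(members, function(m)
        t %in% m, logical(1)))),
        sprintf("fill%d", t)))
    bl <- data.frame(
      block_id = c(sprintf("s%d", seq_along(members)),
                   sprintf("fill%d", 1:k)),
      length = c(blen, lens - vapply(1:k, function(t)
        sum(blen[vapply(members, function(m) t %in% m, logical(1))]),
        numeric(1))),
      pad = FALSE)
    if (any(bl$length < 1)) next
    ann <- annotation(tx, bl, validate = FALSE)

    rd <- read_set(
      origin = rep(ids[vapply(site_members, `[`, integer(1), 1L)],
                   site_counts),
      block = rep(sprintf("s%d", which(keep)), site_counts))
    x <- assign_reads(rd, ann, em_max_iter = 5000L, em_tol = 1e-12)
    th_em <- (x / lens) / sum(x / lens)

    oracle <- grid_ml(lens, site_members, site_blen, site_counts)
    ll_em <- block_loglik(th_em, lens, site_members, site_blen, site_counts)
    expect_gte(ll_em, oracle$loglik - 1e-4)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("tpm conservation, depth invariance and the removal law hold", {
  p <- desk_pipeline(n_genes = 80L, n_reads = 1e4, seed = 21)
  expect_equal(sum(p$fq$tpm), 1e6, tolerance = 1e-6)
  expect_equal(sum(p$fq$reads), attr(p$fq, "n_mapped"), tolerance = 1e-9)

  # duplicating every read leaves tpm unchanged
  dup <- read_set(origin = rep(p$reads$origin, 2), block = rep(p$reads$block, 2))
  qd <- quantify_sample(dup, p$ann)
  expect_equal(qd$tpm, p$fq$tpm, tolerance = 1e-9)
  expect_equal(attr(qd, "n_mapped"), 2 * attr(p$fq, "n_mapped"))

  # removal law: drop zero-read transcripts with no shared compatibility
  ann <- toy_annotation()
  tr <- expression_truth(setNames(c(0.6, 0.2, 0.2, 0), c("A1", "A2", "B1", "C1")))
  rs <- simulate_reads(tr, ann, 4000, seed = 8)
  full_q <- quantify_sample(rs, ann)
  sub <- tpmdepth:::subset_annotation(ann, c("A1", "A2", "B1"))
  sub_q <- quantify_sample(rs, sub)
  m <- match(sub_q$transcript_id, full_q$transcript_id)
  expect_equal(sub_q$reads, full_q$reads[m], tolerance = 1e-9)
  ratio <- quant_S(full_q) / quant_S(sub_q)
  expect_equal(sub_q$tpm, full_q$tpm[m] * ratio, tolerance = 1e-9 * 1e6)
  expect_true(ratio >= 1)
})

test_that("gene tpm recovers ground truth on the full annotation", {
  ann <- forge_transcriptome(300, seed = 6)
  tr <- simulate_expression(ann, seed = 7)
  rs <- simulate_reads(tr, ann, 1e6, seed = 8)
  fg <- summarize_to_gene(quantify_sample(rs, ann), ann, ann)
  gene_theta <- tapply(tr$theta,
                       ann$transcripts$gene_id[match(names(tr$theta),
                                                     ann$transcripts$transcript_id)],
                       sum)
  rho <- cor(gene_theta[fg$gene_id], fg$tpm, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("summarize_to_gene sums members and computes length fractions", {
  ann <- toy_annotation()
  q <- compute_tpm(setNames(c(3, 1, 4, 2), c("A1", "A2", "B1", "C1")),
                   tx_lengths(ann))
  g <- summarize_to_gene(q, ann, ann)
  expect_equal(g$tpm[g$gene_id == "gA"],
               sum(q$tpm[q$transcript_id %in% c("A1", "A2")]))
  expect_equal(g$reads[g$gene_id == "gA"], 4)
  expect_equal(g$represented_length_fraction, rep(1, 3))

  sub <- tpmdepth:::subset_annotation(ann, c("A1", "B1", "C1"))
  qs <- compute_tpm(setNames(c(3, 4, 2), c("A1", "B1", "C1")),
                    tx_lengths(sub))
  gs <- summarize_to_gene(qs, sub, ann)
  expect_equal(gs$represented_length_fraction[gs$gene_id == "gA"], 300 / 500)
  expect_error(summarize_to_gene(q, sub, ann), class = "tpmdepth_input_error")
})

test_that("gene-level summation rescues isoform competition multi-modality", {
  # gene with two isoforms sharing a core; replicate annotations toggle the
  # competitor isoform at random, stratifying transcript-level tpm
  tx <- data.frame(
    transcript_id = c("X1", "X2", "Y1"), gene_id = c("gX", "gX", "gY"),
    family_id = c("gX", "gX", "gY"), length = c(1000L, 1000L, 1000L))
  tx$blocks <- list(c("core", "px1"), c("core", "px2"), "y")
  bl <- data.frame(block_id = c("core", "px1", "px2", "y"),
                   length = c(800L, 200L, 200L, 1000L), pad = FALSE)
  ann <- annotation(tx, bl)
  tr <- expression_truth(setNames(c(0.25, 0.25, 0.5), c("X1", "X2", "Y1")))
  rs <- simulate_reads(tr, ann, 5000, seed = 12)
  tx_tpm <- gene_tpm <- numeric(60)
  present <- withr::with_seed(13, runif(60) < 0.5)
  for (i in 1:60) {
    keep <- if (present[i]) c("X1", "X2", "Y1") else c("X1", "Y1")
    sub <- tpmdepth:::subset_annotation(ann, keep)
    q <- quantify_sample(rs, sub)
    g <- summarize_to_gene(q, sub, ann)
    tx_tpm[i] <- q$tpm[q$transcript_id == "X1"]
    gene_tpm[i] <- g$tpm[g$gene_id == "gX"]
  }
  expect_lt(var(gene_tpm), var(tx_tpm))
})
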