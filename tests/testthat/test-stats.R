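# Minimal gene_quant constructor for fixture-level tests.
make_gene_quant <- function(gene_id, reads, tpm, rlf = 1, S = 1,
                            label = "fix") {
  structure(data.frame(gene_id = gene_id, reads = reads, tpm = tpm,
                       represented_length_fraction = rlf,
                       stringsAsFactors = FALSE),
            S = S, n_mapped = sum(reads), label = label,
            class = c("gene_quant", "data.frame"))
}

test_that("stratified_select_genes draws one gene per occupied bin", {
  gq <- make_gene_quant(sprintf("g%02d", 1:40),
                        reads = rep(10, 40),
                        tpm = 10^seq(0.55, 4.45, length.out = 40))
  sel <- stratified_select_genes(gq, n_bins = 10, seed = 1)
  expect_equal(length(sel), 10L)
  expect_identical(sel, stratified_select_genes(gq, n_bins = 10, seed = 1))
  # one gene per bin
  bins <- findInterval(log10(gq$tpm[match(sel, gq$gene_id)]),
                       seq(0.5, 4.5, length.out = 11))
  expect_equal(sort(unique(pmin(bins, 10))), 1:10)

  # an edge value belongs to the upper (left-closed) bin
  gq2 <- make_gene_quant(c("lo", "edge"), c(5, 5), c(10^0.7, 10^0.9))
  # 0.9 is the edge between bins 1 and 2 -> bin 2, so both bins occupied
  expect_warning(sel2 <- stratified_select_genes(gq2, n_bins = 10, seed = 3),
                 "empty")
  expect_setequal(sel2, c("lo", "edge"))

  # a single in-range gene is selected regardless of seed
  gq3 <- make_gene_quant(c("only", "out"), c(5, 5), c(100, 10^5))
  suppressWarnings({
    s1 <- stratified_select_genes(gq3, n_bins = 10, seed = 1)
    s2 <- stratified_select_genes(gq3, n_bins = 10, seed = 99)
  })
  expect_identical(s1, "only")
  expect_identical(s1, s2)
  expect_error(stratified_select_genes(
    make_gene_quant("g", 5, 10^6), n_bins = 10), class = "tpmdepth_input_error")
})

test_that("build_sweep_result: identity subsample is all zeros, dropouts flagged", {
  full <- make_gene_quant(c("a", "b", "c"), c(10, 20, 30), c(1e5, 3e5, 6e5),
                          S = 0.02)
  same <- make_gene_quant(c("a", "b", "c"), c(10, 20, 30), c(1e5, 3e5, 6e5),
                          S = 0.02)
  res <- build_sweep_result(list(s1 = same), full, c("a", "b", "c"),
                            manifest = data.frame(label = "s1", fraction = 50,
                                                  rep = 1))
  expect_equal(res$log10_tpm_diff, c(0, 0, 0))
  expect_equal(res$log10_reads_diff, c(0, 0, 0))
  expect_false(any(res$dropout))

  zero <- make_gene_quant(c("a", "b", "c"), c(10, 0, 30), c(2e5, 0, 8e5),
                          S = 0.015)
  res2 <- build_sweep_result(list(s2 = zero), full, c("a", "b", "c"),
                             manifest = data.frame(label = "s2", fraction = 30,
                                                   rep = 1))
  expect_true(res2$dropout[res2$gene_id == "b"])
  expect_true(is.na(res2$log10_tpm_diff[res2$gene_id == "b"]))
  expect_error(build_sweep_result(list(s1 = same), full, "zz"),
               class = "tpmdepth_input_error")
})

test_that("zero-read disjoint removal shows up as a pure denominator shift", {
  ann <- toy_annotation()
  tr <- expression_truth(setNames(c(0.5, 0.3, 0.2, 0),
                                  c("A1", "A2", "B1", "C1")))
  rs <- simulate_reads(tr, ann, 3000, seed = 19)
  fq <- quantify_sample(rs, ann)
  fg <- summarize_to_gene(fq, ann, ann)
  sub <- tpmdepth:::subset_annotation(ann, c("A1", "A2", "B1"), label = "sub")
  sq <- quantify_sample(rs, sub)
  sg <- summarize_to_gene(sq, sub, ann)
  res <- build_sweep_result(list(sub = sg), fg, c("gA", "gB"),
                            manifest = data.frame(label = "sub", fraction = 75,
                                                  rep = 1))
  shift <- log10(quant_S(fq) / quant_S(sq))
  expect_equal(res$log10_tpm_diff, rep(shift, 2), tolerance = 1e-9)
  expect_equal(res$log10_reads_diff, c(0, 0), tolerance = 1e-9)

  diag <- denominator_diagnostic(list(sub = sg), fg, c("gA", "gB"))
  expect_true(all(diag$law_holds))
  expect_equal(diag$tpm_ratio, diag$S_ratio, tolerance = 1e-9)
})

test_that("inflation_significance: flat data no calls, shifted fraction called", {
  set.seed(61)
  flat <- structure(data.frame(
    fraction = rep(c(10, 30, 50, 90), each = 40),
    rep = rep(1:40, 4), gene_id = "g",
    log10_tpm_diff = rep(0.42, 160),
    log10_reads_diff = 0, S_sub = 1,
    represented_length_fraction = 1, dropout = FALSE),
    class = c("sweep_result", "data.frame"))
  sig <- inflation_significance(flat)
  expect_false(any(sig$call))

  shifted <- flat
  shifted$log10_tpm_diff <- rnorm(160, 0, 0.01)
  shifted$log10_tpm_diff[shifted$fraction == 10] <-
    shifted$log10_tpm_diff[shifted$fraction == 10] + 1
  sig2 <- inflation_significance(shifted)
  expect_true(sig2$call[sig2$fraction == 10])
  expect_false(any(sig2$call[sig2$fraction %in% c(30, 50)]))

  # two-group case: Kruskal-Wallis H equals the squared Dunn z
  two <- shifted[shifted$fraction %in% c(10, 90), ]
  sig3 <- inflation_significance(two)
  expect_equal(unname(attr(sig3, "kw")$statistic), sig3$z^2,
               tolerance = 1e-9)

  expect_error(inflation_significance(flat[flat$fraction == 10, ]),
               class = "tpmdepth_input_error")
})

test_that("sweep inflation is directional at reduced scale", {
  p <- desk_pipeline(n_genes = 150L, n_reads = 3e4, seed = 81)
  ctrl <- suppressWarnings(
    stratified_select_genes(p$fg, 10, seed = 82))
  keep <- p$ann$transcripts$transcript_id[p$ann$transcripts$gene_id %in% ctrl]
  sch <- sweep_scheme(fractions = c(10, 50, 90), reps_per_fraction = 10,
                      keep_set = keep, seed = 83)
  anns <- subsample_sweep(p$ann, sch)
  gq <- lapply(anns, function(a)
    summarize_to_gene(quantify_sample(p$reads, a), a, p$ann))
  attr(gq, "manifest") <- attr(anns, "manifest")
  res <- build_sweep_result(gq, p$fg, ctrl)
  ok <- !res$dropout & is.finite(res$log10_tpm_diff)
  md <- tapply(res$log10_tpm_diff[ok], res$fraction[ok], mean)
  expect_true(all(md >= 0))
  expect_gt(md[["10"]], md[["90"]])

  # denominator S and control-gene tpm are inversely related
  diag <- denominator_diagnostic(gq, p$fg, ctrl)
  rho <- cor(diag$S_sub, diag$tpm, method = "spearman")
  expect_lt(rho, 0)
})

test_that("characterize_inflated_genes flags competitor-loss genes", {
  # nothing above threshold -> empty set, NA percentile
  full <- make_gene_quant(c("a", "b"), c(10, 10), c(5e5, 5e5))
  same <- make_gene_quant(c("a", "b"), c(10, 10), c(5e5, 5e5))
  ch0 <- characterize_inflated_genes(list(same), full, n_perm = 10)
  expect_length(ch0$flagged, 0)
  expect_true(is.na(ch0$percentile))

  fx <- competitor_fixture(n_background = 60L, seed = 3)
  rs <- simulate_reads(fx$truth, fx$ann, 5e4, seed = 4)
  pc <- preclinicalize(fx$ann, fx$profile, reps = 12, seed = 5)
  oq <- summarize_to_gene(quantify_sample(rs, pc$ortholog_full),
                          pc$ortholog_full, fx$ann)
  gq <- lapply(pc$reduced, function(a)
    summarize_to_gene(quantify_sample(rs, a), a, fx$ann))
  ch <- characterize_inflated_genes(gq, oq, n_perm = 500, seed = 6)
  expect_true("tgt" %in% ch$flagged)
  # the flagged gene gained mapped reads versus the full annotation
  pg <- ch$per_gene[ch$per_gene$gene_id == "tgt", ]
  expect_gt(pg$mean_log10_reads_diff, 0)
  # and sits in the lower tail of equal-size random expression draws
  expect_lt(ch$percentile, 5)
})
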