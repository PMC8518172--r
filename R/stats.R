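# Analysis computations: control-gene selection, the sweep difference
# table, inflation significance (Kruskal-Wallis + Dunn's post hoc with BH
# adjustment), the denominator diagnostic, and the characterization of
# genes inflated in pre-clinicalized annotations.

#' Stratified selection of control genes by expression magnitude
#'
#' Partitions the log10 gene-tpm interval into equal-width bins and draws
#' one gene uniformly from every non-empty bin. A value exactly on an
#' interior bin edge belongs to the upper bin (left-closed bins; the last
#' bin is closed on both sides).
#'
#' @param gene_quant a `gene_quant` of the full annotation
#' @param n_bins number of bins (default 10)
#' @param bin_range_log10 log10 tpm interval covered by the bins (default
#'   `c(0.5, 4.5)`)
#' @param seed integer seed
#' @return character vector of selected gene ids (one per occupied bin)
#' @export
stratified_select_genes <- function(gene_quant, n_bins = 10L,
                                    bin_range_log10 = c(0.5, 4.5),
                                    seed = 1L) {
  if (n_bins < 1L) stop_input("n_bins must be >= 1")
  if (length(bin_range_log10) != 2L || diff(bin_range_log10) <= 0)
    stop_input("bin_range_log10 must be an increasing interval")
  lt <- log10(gene_quant$tpm)
  edges <- seq(bin_range_log10[1], bin_range_log10[2], length.out = n_bins + 1L)
  inside <- lt >= edges[1] & lt <= edges[n_bins + 1L]
  if (!any(inside)) stop_input("no gene falls inside the bin range")
  bin <- pmin(findInterval(lt[inside], edges, left.open = FALSE), n_bins)
  genes <- gene_quant$gene_id[inside]
  withr::with_seed(seed, {
    out <- character(0)
    for (b in seq_len(n_bins)) {
      cand <- genes[bin == b]
      if (length(cand) == 0L) {
        warning(sprintf("bin %d of [%g, %g] is empty; skipped", b,
                        edges[b], edges[b + 1L]))
        next
      }
      out <- c(out, cand[sample.int(length(cand), 1L)])
    }
    out
  })
}

#' Build the sweep difference table
#'
#' For every subsample quantification and every test gene, records the
#' log10 differences in gene tpm and gene mapped reads against the full
#' annotation, the subsample denominator S, and the represented length
#' fraction. Genes with zero tpm in a subsample get a sentinel row with
#' `dropout = TRUE` and `NA` differences.
#'
#' @param sweep_gene_quants named list of `gene_quant` objects, one per
#'   subsample; a `manifest` data.frame (label, fraction, rep) attribute or
#'   a `manifest` argument supplies fraction/rep per label
#' @param full_gene_quant `gene_quant` of the full annotation
#' @param test_genes character vector of gene ids (must exist in the full
#'   quantification)
#' @param manifest optional data.frame (label, fraction, rep)
#' @return a `sweep_result` data.frame with columns fraction, rep, gene_id,
#'   log10_tpm_diff, log10_reads_diff, S_sub, represented_length_fraction,
#'   dropout
#' @export
build_sweep_result <- function(sweep_gene_quants, full_gene_quant,
                               test_genes, manifest = NULL) {
  manifest <- manifest %||% attr(sweep_gene_quants, "manifest")
  if (is.null(manifest))
    manifest <- data.frame(label = names(sweep_gene_quants),
                           fraction = NA_real_,
                           rep = seq_along(sweep_gene_quants),
                           stringsAsFactors = FALSE)
  if (!all(test_genes %in% full_gene_quant$gene_id))
    stop_input("test gene missing from the full quantification")
  fm <- match(test_genes, full_gene_quant$gene_id)
  full_tpm <- full_gene_quant$tpm[fm]
  full_reads <- full_gene_quant$reads[fm]
  rows <- vector("list", length(sweep_gene_quants))
  for (i in seq_along(sweep_gene_quants)) {
    gq <- sweep_gene_quants[[i]]
    lab <- names(sweep_gene_quants)[i]
    mi <- match(lab, manifest$label)
    m <- match(test_genes, gq$gene_id)
    if (anyNA(m)) stop_input("test gene missing from subsample ", lab)
    tpm <- gq$tpm[m]; reads <- gq$reads[m]
    drop <- tpm <= 0
    rows[[i]] <- data.frame(
      fraction = manifest$fraction[mi], rep = manifest$rep[mi],
      gene_id = test_genes,
      log10_tpm_diff = ifelse(drop, NA_real_, log10(tpm) - log10(full_tpm)),
      log10_reads_diff = ifelse(drop | reads <= 0 | full_reads <= 0,
                                NA_real_, log10(reads) - log10(full_reads)),
      S_sub = quant_S(gq),
      represented_length_fraction = gq$represented_length_fraction[m],
      dropout = drop, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            S_full = quant_S(full_gene_quant),
            class = c("sweep_result", "data.frame"))
}

# Dunn's post-hoc z statistic of group i against group j, from pooled ranks
# with tie correction. Standard large-sample formulation.
dunn_z <- function(ranks, groups, gi, gj) {
  N <- length(ranks)
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  ni <- sum(groups == gi); nj <- sum(groups == gj)
  mi <- mean(ranks[groups == gi]); mj <- mean(ranks[groups == gj])
  vr <- (N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj)
  if (vr <= 0) return(0)         # fully tied data carry no evidence
  (mi - mj) / sqrt(vr)
}

#' Significance of tpm inflation across sweep fractions
#'
#' Kruskal-Wallis test of `log10_tpm_diff` across fraction groups, followed
#' by Dunn's post hoc of every fraction against the reference fraction
#' (default: the largest fraction, i.e. divergence from the nearly-full
#' annotation), with Benjamini-Hochberg adjustment. Dropout rows are
#' excluded from the tests and tallied separately.
#'
#' @param result a `sweep_result`
#' @param alpha significance level for the calls (default 0.05)
#' @param reference reference fraction (default `max(fractions)`)
#' @param all_pairs if `TRUE`, run all pairwise Dunn comparisons instead of
#'   versus-reference
#' @return data.frame (fraction, n, z, p_raw, p_adj, call) with attributes
#'   `kw` (the Kruskal-Wallis htest) and `dropouts` (per-fraction dropout
#'   counts); in all-pairs mode the first two columns are fraction_a and
#'   fraction_b
#' @export
inflation_significance <- function(result, alpha = 0.05, reference = NULL,
                                   all_pairs = FALSE) {
  d <- result[!result$dropout & is.finite(result$log10_tpm_diff), ]
  fr <- sort(unique(d$fraction))
  if (length(fr) < 2L) stop_input("need >= 2 fractions with observations")
  if (any(table(d$fraction) < 2L)) stop_input("a fraction has < 2 observations")
  kw <- kruskal.test(d$log10_tpm_diff, factor(d$fraction))
  ranks <- rank(d$log10_tpm_diff)
  groups <- d$fraction
  if (all_pairs) {
    pr <- t(utils::combn(fr, 2))
    z <- apply(pr, 1, function(p) dunn_z(ranks, groups, p[1], p[2]))
    out <- data.frame(fraction_a = pr[, 1], fraction_b = pr[, 2], z = z)
  } else {
    reference <- reference %||% max(fr)
    if (!reference %in% fr) stop_input("reference fraction has no data")
    test_fr <- setdiff(fr, reference)
    z <- vapply(test_fr, function(f) dunn_z(ranks, groups, f, reference),
                numeric(1))
    out <- data.frame(fraction = test_fr,
                      n = as.integer(table(factor(groups, levels = fr))[as.character(test_fr)]),
                      z = z)
  }
  out$p_raw <- 2 * pnorm(-abs(out$z))
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$call <- out$p_adj < alpha
  drops <- tapply(result$dropout, result$fraction, sum)
  structure(out, kw = kw, dropouts = drops, alpha = alpha)
}

#' Denominator diagnostic: the inverse S-tpm relationship
#'
#' Tabulates the sample denominator S against test-gene tpm across a set of
#' quantifications, and, for every (quantification, gene) pair whose mapped
#' reads agree with the full annotation, verifies the closed-form removal
#' law `tpm_sub / tpm_full = S_full / S_sub` to 1e-9 relative.
#'
#' @param gene_quants named list of `gene_quant` objects (>= 2, or >= 1
#'   plus the full quantification)
#' @param full_gene_quant `gene_quant` of the full annotation
#' @param test_genes gene ids to tabulate
#' @return data.frame (label, S_sub, gene_id, reads, tpm, tpm_ratio,
#'   S_ratio, law_holds); `law_holds` is `NA` when counts differ and the
#'   law does not apply
#' @export
denominator_diagnostic <- function(gene_quants, full_gene_quant, test_genes) {
  if (length(gene_quants) + 1L < 2L) stop_input("need >= 2 quantifications")
  fm <- match(test_genes, full_gene_quant$gene_id)
  if (anyNA(fm)) stop_input("test gene missing from the full quantification")
  S_full <- quant_S(full_gene_quant)
  rows <- lapply(seq_along(gene_quants), function(i) {
    gq <- gene_quants[[i]]
    m <- match(test_genes, gq$gene_id)
    tpm <- gq$tpm[m]; reads <- gq$reads[m]
    tpm_ratio <- tpm / full_gene_quant$tpm[fm]
    S_ratio <- S_full / quant_S(gq)
    const <- abs(reads - full_gene_quant$reads[fm]) < 1e-9 & reads > 0
    data.frame(label = names(gene_quants)[i] %||% as.character(i),
               S_sub = quant_S(gq), gene_id = test_genes,
               reads = reads, tpm = tpm,
               tpm_ratio = tpm_ratio, S_ratio = S_ratio,
               law_holds = ifelse(const,
                                  abs(tpm_ratio / S_ratio - 1) < 1e-9, NA),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Characterize genes with inflated tpm in pre-clinicalized annotations
#'
#' Flags genes whose mean log10 tpm difference (reduced versus full
#' ortholog annotation, averaged over replicates) exceeds `threshold` while
#' mean log10 reads difference is positive — i.e. genes that *gain* mapped
#' reads when competitor transcripts disappear. The flagged set's mean
#' full-annotation log10 expression is then compared against `n_perm`
#' equal-size random gene draws; the paper-direction expectation is that
#' inflated genes sit in the lower expression tail.
#'
#' @param preclin_gene_quants list of `gene_quant` objects, one per reduced
#'   replicate
#' @param full_gene_quant `gene_quant` of the full (ortholog) annotation
#' @param n_perm number of random draws (default 1000)
#' @param seed integer seed for the permutation draws
#' @param threshold mean log10 tpm difference above which a gene is flagged
#'   (default 0.1)
#' @return list with `flagged` (gene ids), `per_gene` (data.frame of mean
#'   differences), `obs_mean_log10_tpm`, `perm_means`, `percentile`
#'   (permutation percentile of the flagged set's mean expression; `NA`
#'   when nothing is flagged), and `length_fraction_profile`
#' @export
characterize_inflated_genes <- function(preclin_gene_quants, full_gene_quant,
                                        n_perm = 1000L, seed = 1L,
                                        threshold = 0.1) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  genes <- full_gene_quant$gene_id
  acc_t <- acc_r <- acc_n <- setNames(numeric(length(genes)), genes)
  acc_rlf <- setNames(numeric(length(genes)), genes)
  for (gq in preclin_gene_quants) {
    m <- match(genes, gq$gene_id)
    tpm <- gq$tpm[m]; reads <- gq$reads[m]
    ok <- !is.na(tpm) & tpm > 0 & full_gene_quant$tpm > 0
    dt <- log10(tpm[ok]) - log10(full_gene_quant$tpm[ok])
    dr <- log10(pmax(reads[ok], 0.5)) - log10(pmax(full_gene_quant$reads[ok], 0.5))
    acc_t[ok] <- acc_t[ok] + dt
    acc_r[ok] <- acc_r[ok] + dr
    acc_n[ok] <- acc_n[ok] + 1
    acc_rlf[ok] <- acc_rlf[ok] + gq$represented_length_fraction[m][ok]
  }
  seen <- acc_n > 0
  per_gene <- data.frame(
    gene_id = genes[seen],
    mean_log10_tpm_diff = acc_t[seen] / acc_n[seen],
    mean_log10_reads_diff = acc_r[seen] / acc_n[seen],
    mean_represented_length_fraction = acc_rlf[seen] / acc_n[seen],
    n_reps = acc_n[seen], stringsAsFactors = FALSE)
  flagged <- per_gene$gene_id[per_gene$mean_log10_tpm_diff > threshold &
                                per_gene$mean_log10_reads_diff > 0]
  if (length(flagged) == 0L) {
    return(list(flagged = character(), per_gene = per_gene,
                obs_mean_log10_tpm = NA_real_, perm_means = numeric(),
                percentile = NA_real_,
                length_fraction_profile = per_gene[0, ]))
  }
  expressed <- genes[full_gene_quant$tpm > 0]
  obs <- mean(log10(full_gene_quant$tpm[match(flagged, genes)]))
  perm_means <- withr::with_seed(seed, {
    lf <- log10(full_gene_quant$tpm[match(expressed, genes)])
    vapply(seq_len(n_perm), function(i)
      mean(lf[sample.int(length(lf), length(flagged))]), numeric(1))
  })
  list(flagged = flagged, per_gene = per_gene,
       obs_mean_log10_tpm = obs, perm_means = perm_means,
       percentile = 100 * mean(perm_means <= obs),
       length_fraction_profile =
         per_gene[per_gene$gene_id %in% flagged, ])
}
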