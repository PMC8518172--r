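# Trimmed mean of M-values (TMM) computed from its defining formulas, and
# its application to tpm tables over orthologous, expressed genes. TMM
# assumes that the majority of genes are not differentially expressed
# between the compared samples, which is the standing assumption for
# same-tissue cross-species comparison.

#' TMM scaling factor between two expression vectors
#'
#' Computes the trimmed mean of M-values of `test_expr` against `ref_expr`.
#' Values are first normalized by their column sums (library sizes; here,
#' tpm column sums); genes with zero in either sample are dropped. M (log2
#' ratio) and A (average log2 expression) are formed, the most extreme
#' `logratio_trim` of M and `abs_expr_trim` of A are discarded on each side,
#' and the factor is 2 to the precision-weighted mean of the surviving M,
#' with inverse delta-method variances `(N - x) / (N x)` summed over the
#' two samples as weights.
#'
#' A sample against itself gives factor 1 exactly, as does a pure depth
#' change (`test = c * ref`), since library-size normalization cancels any
#' global multiplier before M is formed.
#'
#' @param ref_expr,test_expr non-negative expression vectors aligned on the
#'   same gene set (names optional but, if present, must match)
#' @param logratio_trim two-sided trim fraction on M (default 0.30)
#' @param abs_expr_trim two-sided trim fraction on A (default 0.05)
#' @param min_genes minimum genes surviving the double trim (default 3)
#' @return a `tmm_result`: list with `factor`, `logratio_trim`,
#'   `abs_expr_trim`, `genes_used` (ids or indices of surviving genes),
#'   `lib_ref`, `lib_test`
#' @export
tmm_factor <- function(ref_expr, test_expr, logratio_trim = 0.30,
                       abs_expr_trim = 0.05, min_genes = 3L) {
  if (length(ref_expr) != length(test_expr))
    stop_input("vectors must be aligned on the same gene set")
  if (!is.null(names(ref_expr)) && !is.null(names(test_expr)) &&
      !identical(names(ref_expr), names(test_expr)))
    stop_input("gene names of the two vectors disagree")
  if (any(ref_expr < 0) || any(test_expr < 0))
    stop_input("expression values must be non-negative")
  nR <- sum(ref_expr); nT <- sum(test_expr)
  if (nR <= 0 || nT <= 0) stop_input("a sample has zero total expression")
  ok <- ref_expr > 0 & test_expr > 0
  ids <- names(ref_expr) %||% as.character(seq_along(ref_expr))
  r <- ref_expr[ok]; t <- test_expr[ok]; ids <- ids[ok]
  n <- length(r)
  if (n < min_genes) stop_input("fewer than ", min_genes,
                                " genes survive the positivity filter")
  pT <- t / nT; pR <- r / nR
  M <- log2(pT / pR)
  A <- 0.5 * (log2(pT) + log2(pR))
  # delta-method precision on the proportion scale: scale-free, so the
  # factor is exactly invariant to multiplying one sample by a constant;
  # coincides with the count-based weighting when library sizes are equal
  v <- (1 - pT) / pT + (1 - pR) / pR
  # double trim by rank, symmetric in each tail (edgeR-style cutoffs)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_expr_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < min_genes)
    stop_input("fewer than ", min_genes, " genes survive the double trim")
  w <- 1 / v[keep]
  f <- sum(w * M[keep]) / sum(w)
  structure(list(factor = 2^f, logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim, genes_used = ids[keep],
                 lib_ref = nR, lib_test = nT),
            class = "tmm_result")
}

#' @export
print.tmm_result <- function(x, ...) {
  cat(sprintf("TMM factor %.6f (%d genes used; trims M=%.2f, A=%.2f)\n",
              x$factor, length(x$genes_used), x$logratio_trim,
              x$abs_expr_trim))
  invisible(x)
}

# Upper-quartile-of-positive-values reference selection (the canonical
# convention): the sample whose UQ is closest to the mean UQ.
pick_reference <- function(mat) {
  uq <- apply(mat, 2, function(v) quantile(v[v > 0], 0.75, names = FALSE))
  which.min(abs(uq - mean(uq)))
}

#' Cross-species tpm correction over orthologous genes
#'
#' Implements the correction workflow: restrict to one-to-one orthologs,
#' keep genes above the tpm floor (strictly) in both members of each
#' compared pair, compute a TMM factor for every sample against the human
#' reference sample, rescale every sample by
#' `(lib_ref / lib_sample) / factor` (one multiplier per sample, so gene
#' rank order is untouched), and report per-sample distributions of
#' `log10(tpm) - log10(median human tpm)` before and after correction.
#'
#' @param human numeric matrix of human tpm (genes x samples, rownames =
#'   reference gene ids)
#' @param species numeric matrix of species tpm (genes x samples, rownames
#'   = species gene ids, translated via `ortholog_map`)
#' @param ortholog_map data.frame with columns `gene_ref`, `gene_other`
#'   (one-to-one); pass `NULL` when `species` already uses reference ids
#' @param tpm_floor expression floor; genes must exceed it strictly in both
#'   members of a pair to enter the M/A computation (default 1)
#' @param tissue_human,tissue_species optional character vectors (one per
#'   column) assigning samples to tissues; TMM and medians are then
#'   computed within tissue (the default framing), and every tissue must
#'   contain at least one human sample
#' @param logratio_trim,abs_expr_trim trim parameters, see [tmm_factor()]
#' @return an `xspecies_norm` list: `human_corrected`, `species_corrected`
#'   (matrices over ortholog genes), `factors` (data.frame sample, side,
#'   tissue, tmm_factor, scaling, ref_sample), `diagnostics` (data.frame
#'   sample, side, tissue, stage = pre|post, median_log10_diff, n_genes),
#'   `gene_diffs` (per-gene log10 differences, tidy), `ortholog_genes`
#' @export
normalize_cross_species <- function(human, species, ortholog_map = NULL,
                                    tpm_floor = 1,
                                    tissue_human = NULL,
                                    tissue_species = NULL,
                                    logratio_trim = 0.30,
                                    abs_expr_trim = 0.05) {
  human <- as.matrix(human); species <- as.matrix(species)
  if (tpm_floor < 0) stop_input("tpm_floor must be >= 0")
  if (is.null(colnames(human)))
    colnames(human) <- sprintf("human_%d", seq_len(ncol(human)))
  if (is.null(colnames(species)))
    colnames(species) <- sprintf("species_%d", seq_len(ncol(species)))
  if (!is.null(ortholog_map)) {
    if (anyDuplicated(ortholog_map$gene_ref) ||
        anyDuplicated(ortholog_map$gene_other))
      stop_input("ortholog map must be one-to-one")
    m <- match(rownames(species), ortholog_map$gene_other)
    species <- species[!is.na(m), , drop = FALSE]
    rownames(species) <- ortholog_map$gene_ref[m[!is.na(m)]]
  }
  orth <- intersect(rownames(human), rownames(species))
  if (length(orth) == 0L) stop_input("empty ortholog intersection")
  human <- human[orth, , drop = FALSE]
  species <- species[orth, , drop = FALSE]
  tissue_human <- tissue_human %||% rep("all", ncol(human))
  tissue_species <- tissue_species %||% rep("all", ncol(species))
  if (length(tissue_human) != ncol(human) ||
      length(tissue_species) != ncol(species))
    stop_input("tissue vectors must have one entry per sample column")

  hc <- human; sc <- species
  fac_rows <- list(); diff_rows <- list(); gd_rows <- list()
  for (tis in unique(c(tissue_human, tissue_species))) {
    h_i <- which(tissue_human == tis)
    s_i <- which(tissue_species == tis)
    if (length(h_i) == 0L)
      stop_input("tissue '", tis, "' has no human reference sample")
    ref_j <- h_i[pick_reference(human[, h_i, drop = FALSE])]
    ref <- human[, ref_j]
    scale_one <- function(v) {
      pair <- ref > tpm_floor & v > tpm_floor
      if (sum(pair) == 0L) stop_input("no gene passes the tpm floor in a pair")
      tm <- tmm_factor(ref[pair], v[pair], logratio_trim, abs_expr_trim)
      list(tmm = tm$factor, scaling = (tm$lib_ref / tm$lib_test) / tm$factor)
    }
    for (j in h_i) {
      sres <- if (j == ref_j) list(tmm = 1, scaling = 1) else scale_one(human[, j])
      hc[, j] <- human[, j] * sres$scaling
      fac_rows[[length(fac_rows) + 1L]] <- data.frame(
        sample = colnames(human)[j], side = "human", tissue = tis,
        tmm_factor = sres$tmm, scaling = sres$scaling,
        ref_sample = colnames(human)[ref_j], stringsAsFactors = FALSE)
    }
    for (j in s_i) {
      sres <- scale_one(species[, j])
      sc[, j] <- species[, j] * sres$scaling
      fac_rows[[length(fac_rows) + 1L]] <- data.frame(
        sample = colnames(species)[j], side = "species", tissue = tis,
        tmm_factor = sres$tmm, scaling = sres$scaling,
        ref_sample = colnames(human)[ref_j], stringsAsFactors = FALSE)
    }
    # diagnostics: log10 differences to the median human value, per sample;
    # the gene set (passing the floor in sample and in the human median) is
    # fixed at the pre-correction stage so pre and post are comparable
    med_pre <- apply(human[, h_i, drop = FALSE], 1, median)
    med_post <- apply(hc[, h_i, drop = FALSE], 1, median)
    for (j in s_i) {
      use <- species[, j] > tpm_floor & med_pre > tpm_floor
      if (sum(use) == 0L) next
      g <- orth[use]
      d_pre <- log10(species[use, j]) - log10(med_pre[use])
      d_post <- log10(sc[use, j]) - log10(med_post[use])
      samp <- colnames(species)[j]
      gd_rows[[length(gd_rows) + 1L]] <- data.frame(
        sample = samp, side = "species", tissue = tis,
        gene_id = rep(g, 2L),
        stage = rep(c("pre", "post"), each = length(g)),
        log10_diff = c(d_pre, d_post), stringsAsFactors = FALSE)
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        sample = samp, side = "species", tissue = tis,
        stage = c("pre", "post"),
        median_log10_diff = c(median(d_pre), median(d_post)),
        n_genes = sum(use), stringsAsFactors = FALSE)
    }
  }
  structure(list(human_corrected = hc, species_corrected = sc,
                 factors = do.call(rbind, fac_rows),
                 diagnostics = do.call(rbind, diff_rows),
                 gene_diffs = do.call(rbind, gd_rows),
                 ortholog_genes = orth, tpm_floor = tpm_floor),
            class = "xspecies_norm")
}

#' @export
print.xspecies_norm <- function(x, ...) {
  cat(sprintf("cross-species tpm correction over %d ortholog genes\n",
              length(x$ortholog_genes)))
  print(x$diagnostics)
  invisible(x)
}

#' Housekeeping-gene stability check of a correction
#'
#' Recomputes the per-sample median log10 differences of
#' [normalize_cross_species()] restricted to a housekeeping panel — genes
#' expected to be expressed everywhere, so their differences should sit
#' near zero after a successful correction.
#'
#' @param result an `xspecies_norm`
#' @param housekeeping_genes character vector of reference gene ids
#' @return data.frame (sample, tissue, stage, median_log10_diff, n_genes);
#'   zero rows (with a warning) when the panel does not intersect the
#'   ortholog set
#' @export
housekeeping_check <- function(result, housekeeping_genes) {
  if (!inherits(result, "xspecies_norm"))
    stop_input("result must come from normalize_cross_species()")
  if (length(housekeeping_genes) == 0L)
    stop_input("housekeeping set is empty")
  gd <- result$gene_diffs[result$gene_diffs$gene_id %in% housekeeping_genes, ]
  if (nrow(gd) == 0L) {
    warning("housekeeping panel does not intersect the ortholog gene set")
    return(data.frame(sample = character(), tissue = character(),
                      stage = character(), median_log10_diff = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(log10_diff ~ sample + tissue + stage, data = gd, median)
  cnt <- aggregate(log10_diff ~ sample + tissue + stage, data = gd, length)
  names(agg)[4] <- "median_log10_diff"
  agg$n_genes <- cnt$log10_diff
  agg <- agg[order(agg$sample, agg$tissue, agg$stage), ]
  rownames(agg) <- NULL
  agg
}

#' @importFrom stats aggregate ave
NULL
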