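# Read assignment and tpm computation. This module is the desk-scale
# stand-in for a lightweight quantifier (salmon-like): reads are grouped
# into equivalence classes by compatibility set, uniquely compatible reads
# count 1.0 to their transcript, and ambiguous reads are fractionally
# allocated by EM over per-length relative abundances.

#' Assign reads to transcripts of an annotation
#'
#' Reads whose compatibility set against `ann` is empty are unmapped and
#' excluded from all counts. Uniquely compatible reads contribute a full
#' count; ambiguous reads are split by EM. Fully symmetric transcripts
#' receive equal fractional allocation (uniform EM initialisation).
#'
#' @param reads a [read_set()]
#' @param ann the [annotation()] quantified against
#' @param em_max_iter maximum EM iterations (default 1000)
#' @param em_tol convergence tolerance on the max absolute change in
#'   relative abundance (default 1e-8)
#' @return named numeric vector `x` of expected read counts, one entry per
#'   transcript of `ann` (annotation order); `sum(x)` equals the number of
#'   mapped reads. Attribute `n_unmapped` carries the unmapped read count.
#' @export
assign_reads <- function(reads, ann, em_max_iter = 1000L, em_tol = 1e-8) {
  if (!inherits(ann, "annotation")) stop_input("ann must be an annotation")
  if (em_max_iter < 1L) stop_input("em_max_iter must be >= 1")
  ids <- tx_ids(ann)
  n_tx <- length(ids)
  x <- setNames(numeric(n_tx), ids)
  if (nrow(reads) == 0L) {
    attr(x, "n_unmapped") <- 0L
    return(x)
  }
  idx <- block_tx_index(ann)                    # block -> tx indices
  bl_tab <- table(factor(reads$block, levels = names(idx)))
  n_unmapped <- nrow(reads) - sum(bl_tab)
  present <- names(bl_tab)[bl_tab > 0L]
  if (length(present) == 0L) {
    attr(x, "n_unmapped") <- as.integer(n_unmapped)
    return(x)
  }
  mem_by_block <- idx[present]
  cnt_by_block <- as.numeric(bl_tab[present])
  # collapse blocks with identical compatibility sets into one EC
  key <- vapply(mem_by_block, function(i) paste(i, collapse = ","), character(1))
  grp <- split(seq_along(key), key)
  members_l <- lapply(grp, function(g) mem_by_block[[g[1]]])
  counts <- vapply(grp, function(g) sum(cnt_by_block[g]), numeric(1))
  members <- unlist(members_l, use.names = FALSE) - 1L
  ec_start <- c(0L, cumsum(lengths(members_l)))
  xv <- em_assign(members, as.integer(ec_start), as.numeric(counts),
                  as.numeric(ann$transcripts$length), n_tx,
                  as.integer(em_max_iter), em_tol)
  x[] <- xv
  attr(x, "n_unmapped") <- as.integer(n_unmapped)
  x
}

#' Compute transcripts-per-million from counts and lengths
#'
#' Implements the tpm definition
#' \deqn{tpm_i = 10^6 \frac{x_i / y_i}{\sum_j x_j / y_j}}
#' with raw transcript lengths. The sample denominator
#' \eqn{S = \sum_j x_j / y_j} (reads per nucleotide) is retained because the
#' annotation-depth artifact acts entirely through it: removing annotated
#' transcripts shrinks S and inflates every surviving tpm.
#'
#' @param x numeric vector of mapped-read counts (may be fractional);
#'   names, if present, become transcript ids
#' @param y positive numeric vector of transcript lengths (nt)
#' @param transcript_id optional explicit ids (defaults to `names(x)`)
#' @param label sample/annotation label recorded on the result
#' @return a `sample_quant`: data.frame with columns `transcript_id`,
#'   `reads`, `length`, `tpm`, and attributes `S` (denominator),
#'   `n_mapped`, `label`
#' @examples
#' compute_tpm(c(10, 30), c(100, 100))$tpm  # 250000, 750000
#' @export
compute_tpm <- function(x, y, transcript_id = names(x), label = "sample") {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (any(y <= 0)) stop_input("lengths must be positive")
  if (any(x < 0)) stop_input("counts must be non-negative")
  if (sum(x) == 0) stop_input("no mapped reads: all counts are zero")
  if (is.null(transcript_id)) transcript_id <- sprintf("T%d", seq_along(x))
  n_unmapped <- attr(x, "n_unmapped") %||% NA_integer_
  x <- as.numeric(x); y <- as.numeric(y)
  rate <- x / y
  S <- sum(rate)
  out <- data.frame(transcript_id = transcript_id,
                    reads = x, length = y,
                    tpm = 1e6 * rate / S, stringsAsFactors = FALSE)
  structure(out, S = S, n_mapped = sum(x), label = label,
            n_unmapped = n_unmapped,
            class = c("sample_quant", "data.frame"))
}

#' Quantify a read set against an annotation
#'
#' Convenience wrapper: [assign_reads()] then [compute_tpm()].
#'
#' @inheritParams assign_reads
#' @param label label recorded on the result (defaults to `ann$label`)
#' @return a `sample_quant` (see [compute_tpm()])
#' @export
quantify_sample <- function(reads, ann, em_max_iter = 1000L, em_tol = 1e-8,
                            label = ann$label) {
  x <- assign_reads(reads, ann, em_max_iter = em_max_iter, em_tol = em_tol)
  compute_tpm(x, tx_lengths(ann), label = label)
}

#' Sample denominator of a quantification
#'
#' @param quant a `sample_quant` or `gene_quant`
#' @return the denominator \eqn{S = \sum_j x_j / y_j} in reads per nt
#' @export
quant_S <- function(quant) attr(quant, "S")

#' Summarize a transcript quantification to the gene level
#'
#' Gene counts and tpm are the plain sums over member transcripts (abundance
#' summation, the tximport default). `represented_length_fraction` is the
#' fraction of the gene's full-annotation total transcript length present in
#' the quantified annotation — the covariate that separates read-loss from
#' read-gain genes in reduced annotations.
#'
#' @param quant a `sample_quant` over the transcripts of `ann`
#' @param ann the quantified [annotation()]
#' @param full_ann the full reference [annotation()] (`ann` must be an
#'   id-subset of it)
#' @return a `gene_quant`: data.frame with columns `gene_id`, `reads`,
#'   `tpm`, `represented_length_fraction`; attributes `S`, `n_mapped`,
#'   `label` are carried over
#' @export
summarize_to_gene <- function(quant, ann, full_ann = ann) {
  if (!all(quant$transcript_id %in% tx_ids(ann)))
    stop_input("quant contains transcript ids absent from the annotation")
  if (!all(tx_ids(ann) %in% tx_ids(full_ann)))
    stop_input("annotation is not a subset of the full annotation")
  m <- match(quant$transcript_id, ann$transcripts$transcript_id)
  gene <- ann$transcripts$gene_id[m]
  genes <- sort(unique(gene))
  gf <- factor(gene, levels = genes)
  reads <- as.numeric(rowsum(quant$reads, gf))
  tpm <- as.numeric(rowsum(quant$tpm, gf))
  # represented length: present transcripts vs full annotation, per gene
  ftx <- full_ann$transcripts
  full_len <- tapply(ftx$length, ftx$gene_id, sum)
  pres <- ann$transcripts[ann$transcripts$transcript_id %in% quant$transcript_id, ]
  pres_len <- tapply(pres$length, factor(pres$gene_id, levels = genes), sum)
  rlf <- as.numeric(pres_len) / as.numeric(full_len[genes])
  out <- data.frame(gene_id = genes, reads = reads, tpm = tpm,
                    represented_length_fraction = rlf,
                    stringsAsFactors = FALSE)
  structure(out, S = attr(quant, "S"), n_mapped = attr(quant, "n_mapped"),
            label = attr(quant, "label"),
            class = c("gene_quant", "data.frame"))
}
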