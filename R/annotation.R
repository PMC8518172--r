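# Domain containers. An annotation is the in-memory analogue of a reference
# transcriptome: a transcript table plus a block table. Blocks are abstract
# sequence segments; two transcripts that contain the same block are
# mappably homologous over that segment, which is all the read model needs.

#' Construct an annotation (a versioned transcript set)
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `family_id`, `length` (nt) and a list-column `blocks` of block-id
#'   character vectors. `length` must equal the summed lengths of the
#'   transcript's blocks.
#' @param blocks data.frame with columns `block_id`, `length` and logical
#'   `pad` (padding blocks never attract reads).
#' @param label annotation label, e.g. `"full"` or `"sub_37pct_rep012"`
#' @param version_tag free-form version string
#' @param validate run the (O(n) but not free) structural invariant checks
#' @return an object of class `annotation`
#' @export
annotation <- function(transcripts, blocks, label = "full",
                       version_tag = "1", validate = TRUE) {
  need <- c("transcript_id", "gene_id", "family_id", "length", "blocks")
  if (!all(need %in% names(transcripts)))
    stop_input("annotation: transcript table must have columns ",
               paste(need, collapse = ", "))
  if (!all(c("block_id", "length") %in% names(blocks)))
    stop_input("annotation: block table must have block_id and length")
  if (is.null(blocks$pad)) blocks$pad <- FALSE
  transcripts$length <- as.integer(transcripts$length)
  blocks$length <- as.integer(blocks$length)
  rownames(transcripts) <- NULL
  rownames(blocks) <- NULL
  obj <- structure(list(label = label, version_tag = version_tag,
                        transcripts = transcripts, blocks = blocks),
                   class = "annotation")
  if (validate) validate_annotation(obj)
  obj
}

validate_annotation <- function(ann) {
  tx <- ann$transcripts
  if (nrow(tx) == 0L) stop_input("annotation is empty")
  if (anyDuplicated(tx$transcript_id))
    stop_input("duplicate transcript_ids")
  if (anyDuplicated(ann$blocks$block_id))
    stop_input("duplicate block_ids")
  blen <- setNames(ann$blocks$length, ann$blocks$block_id)
  all_bids <- unlist(tx$blocks, use.names = FALSE)
  if (!all(all_bids %in% names(blen)))
    stop_input("transcript references unknown block_id")
  if (any(tx$length < 1L)) stop_input("transcript length must be >= 1")
  sums <- vapply(tx$blocks, function(b) sum(blen[b]), numeric(1))
  if (!all(sums == tx$length))
    stop_input("transcript length must equal the sum of its block lengths")
  # transcripts of one gene must share at least one block (the gene core)
  for (g in unique(tx$gene_id[duplicated(tx$gene_id)])) {
    bl <- tx$blocks[tx$gene_id == g]
    if (length(Reduce(intersect, bl)) < 1L)
      stop_input("transcripts of gene ", g, " share no block")
  }
  # block sharing across genes only within one paralog family
  pairs <- unique(data.frame(
    block = all_bids,
    family = rep(tx$family_id, lengths(tx$blocks))))
  nfam <- tapply(pairs$family, pairs$block, function(f) length(unique(f)))
  if (any(nfam > 1L))
    stop_input("block shared across distinct paralog families")
  invisible(ann)
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation '%s' (version %s): %d transcripts, %d genes, %d blocks\n",
              x$label, x$version_tag, nrow(x$transcripts),
              length(unique(x$transcripts$gene_id)), nrow(x$blocks)))
  invisible(x)
}

#' Annotation accessors
#'
#' @param ann an [annotation()]
#' @return `tx_ids()`: character vector of transcript ids; `gene_ids()`:
#'   character vector of gene ids; `tx_lengths()`: named integer lengths;
#'   `n_transcripts_per_gene()`: named integer counts.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
tx_ids <- function(ann) ann$transcripts$transcript_id

#' @rdname annotation-accessors
#' @export
gene_ids <- function(ann) unique(ann$transcripts$gene_id)

#' @rdname annotation-accessors
#' @export
tx_lengths <- function(ann)
  setNames(ann$transcripts$length, ann$transcripts$transcript_id)

#' @rdname annotation-accessors
#' @export
n_transcripts_per_gene <- function(ann) {
  tab <- table(ann$transcripts$gene_id)
  setNames(as.integer(tab), names(tab))
}

# Restrict an annotation to a transcript-id subset, keeping only blocks that
# remain referenced. Validation is skipped: subsets of a valid annotation
# remain valid (invariants are hereditary).
subset_annotation <- function(ann, keep_tx, label = ann$label,
                              version_tag = ann$version_tag) {
  tx <- ann$transcripts[match(keep_tx, ann$transcripts$transcript_id), ,
                        drop = FALSE]
  if (anyNA(tx$transcript_id))
    stop_input("subset_annotation: unknown transcript_id")
  used <- unique(unlist(tx$blocks, use.names = FALSE))
  bl <- ann$blocks[ann$blocks$block_id %in% used, , drop = FALSE]
  rownames(tx) <- rownames(bl) <- NULL
  structure(list(label = label, version_tag = version_tag,
                 transcripts = tx, blocks = bl), class = "annotation")
}

# block_id -> integer indices of containing transcripts (within ann order)
block_tx_index <- function(ann) {
  n <- lengths(ann$transcripts$blocks)
  split(rep(seq_len(nrow(ann$transcripts)), n),
        unlist(ann$transcripts$blocks, use.names = FALSE))
}

#' Construct a ground-truth expression profile
#'
#' Molar proportions per transcript; this is the simulation's stand-in for
#' the biological sample that gets sequenced. Proportions are validated to
#' be non-negative and to sum to one within 1e-9 (set `normalize = TRUE` to
#' rescale arbitrary non-negative weights first).
#'
#' @param theta named non-negative numeric vector (names = transcript ids)
#' @param normalize divide by the sum before validating
#' @return object of class `expression_truth`
#' @export
expression_truth <- function(theta, normalize = FALSE) {
  if (is.null(names(theta)) || anyDuplicated(names(theta)))
    stop_input("theta must have unique transcript-id names")
  if (any(theta < 0) || any(!is.finite(theta)))
    stop_input("theta must be finite and non-negative")
  if (normalize) theta <- theta / sum(theta)
  if (abs(sum(theta) - 1) > 1e-9)
    stop_input("theta must sum to 1 within 1e-9")
  structure(list(theta = theta), class = "expression_truth")
}

#' @export
print.expression_truth <- function(x, ...) {
  cat(sprintf("expression_truth over %d transcripts (sum %.9f)\n",
              length(x$theta), sum(x$theta)))
  invisible(x)
}

#' Construct a species annotation profile
#'
#' Describes a "pre-clinical" annotation style relative to a reference
#' annotation: how many transcripts each gene has, and which reference genes
#' have a one-to-one ortholog in the species.
#'
#' @param name species label
#' @param per_gene_transcript_count named integer vector, gene_id -> count
#' @param ortholog_genes character vector of reference gene ids with a
#'   one-to-one ortholog
#' @param reference optional [annotation()] to validate counts against
#' @return object of class `species_profile`
#' @export
species_profile <- function(name, per_gene_transcript_count, ortholog_genes,
                            reference = NULL) {
  cnt <- per_gene_transcript_count
  if (is.null(names(cnt))) stop_input("counts must be named by gene_id")
  if (any(cnt < 1L)) stop_input("per-gene transcript counts must be >= 1")
  if (!is.null(reference)) {
    ref_cnt <- n_transcripts_per_gene(reference)
    if (!all(names(cnt) %in% names(ref_cnt)))
      stop_input("profile names genes absent from the reference")
    if (any(cnt > ref_cnt[names(cnt)]))
      stop_input("profile demands more transcripts than the reference has")
    if (!all(ortholog_genes %in% names(ref_cnt)))
      stop_input("ortholog_genes must be a subset of reference genes")
  }
  structure(list(name = name,
                 per_gene_transcript_count = setNames(as.integer(cnt), names(cnt)),
                 ortholog_genes = unique(ortholog_genes)),
            class = "species_profile")
}

#' Construct a read set
#'
#' A read is abstract: the transcript it originated from and the block it
#' covers. Its compatibility set against any annotation is the set of
#' transcripts in that annotation containing the block.
#'
#' @param origin character vector of originating transcript ids
#' @param block character vector of covered block ids
#' @return data.frame of class `read_set`
#' @export
read_set <- function(origin = character(), block = character()) {
  if (length(origin) != length(block))
    stop_input("origin and block must have equal length")
  structure(data.frame(origin = origin, block = block,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Compatibility sets of reads against an annotation
#'
#' @param reads a [read_set()]
#' @param ann an [annotation()]
#' @return list (one element per read) of character vectors of compatible
#'   transcript ids; empty vector = unmapped against `ann`
#' @export
compatibility <- function(reads, ann) {
  idx <- block_tx_index(ann)
  ids <- tx_ids(ann)
  out <- idx[reads$block]
  lapply(out, function(i) if (is.null(i)) character() else ids[i])
}
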