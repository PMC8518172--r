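# Perturbed annotations: the subsampling sweep, paralog removal,
# pre-clinicalization to species isoform counts, and gene-length drift.

#' Subsampling sweep scheme
#'
#' @param fractions percentage grid, each in (0, 100); default 1-99 by 1
#' @param reps_per_fraction replicate annotations per fraction (default 100)
#' @param keep_set transcript ids removed from the sampling pool before
#'   subdivision and re-inserted into every subsample (the control-
#'   transcript protocol)
#' @param seed integer seed for the whole sweep
#' @return a list of class `sweep_scheme`
#' @export
sweep_scheme <- function(fractions = 1:99, reps_per_fraction = 100L,
                         keep_set = character(), seed = 1L) {
  if (any(fractions <= 0) || any(fractions >= 100))
    stop_config("fractions must lie in (0, 100)")
  if (reps_per_fraction < 1L) stop_config("reps_per_fraction must be >= 1")
  structure(list(fractions = as.numeric(fractions),
                 reps_per_fraction = as.integer(reps_per_fraction),
                 keep_set = unique(keep_set), seed = as.integer(seed)),
            class = "sweep_scheme")
}

#' Random transcript-subsampling sweep
#'
#' For each (fraction, replicate) pair, samples `round(fraction% * pool)`
#' transcripts without replacement from the full annotation minus the
#' `keep_set`, then re-inserts the entire `keep_set`. Labels encode fraction
#' and replicate; the result is deterministic given `scheme$seed`.
#'
#' @param full the full [annotation()]
#' @param scheme a [sweep_scheme()]
#' @return named list of [annotation()] objects, one per (fraction, rep);
#'   attribute `manifest` is a data.frame (label, fraction, rep, n_sampled,
#'   n_total)
#' @export
subsample_sweep <- function(full, scheme) {
  if (!inherits(scheme, "sweep_scheme")) stop_input("scheme must be a sweep_scheme")
  ids <- tx_ids(full)
  if (!all(scheme$keep_set %in% ids))
    stop_input("keep_set contains transcripts absent from the full annotation")
  pool <- setdiff(ids, scheme$keep_set)
  if (length(pool) == 0L) stop_input("sampling pool is empty")
  grid <- expand.grid(rep = seq_len(scheme$reps_per_fraction),
                      fraction = scheme$fractions)[, c("fraction", "rep")]
  out <- vector("list", nrow(grid))
  labels <- character(nrow(grid))
  n_sampled <- integer(nrow(grid))
  withr::with_seed(scheme$seed, {
    for (i in seq_len(nrow(grid))) {
      f <- grid$fraction[i]; r <- grid$rep[i]
      sz <- max(1L, round_half_up(f / 100 * length(pool)))
      sel <- c(pool[sample.int(length(pool), sz)], scheme$keep_set)
      lab <- sprintf("sub_%02.0fpct_rep%03d", f, r)
      out[[i]] <- subset_annotation(full, sel, label = lab)
      labels[i] <- lab
      n_sampled[i] <- sz
    }
  })
  names(out) <- labels
  attr(out, "manifest") <- data.frame(
    label = labels, fraction = grid$fraction, rep = grid$rep,
    n_sampled = n_sampled, n_total = n_sampled + length(scheme$keep_set),
    stringsAsFactors = FALSE)
  out
}

#' Remove paralogous competitor transcripts of target genes
#'
#' Deletes every transcript belonging to the same paralog family as a
#' target gene but to a *different* gene — the cross-gene read-map
#' competitors. The target genes' own transcripts are retained.
#'
#' @param full an [annotation()]
#' @param target_genes character vector of gene ids present in `full`
#' @return an [annotation()] labelled `<label>_noparalogs`
#' @export
remove_paralogs <- function(full, target_genes) {
  tx <- full$transcripts
  if (!all(target_genes %in% tx$gene_id))
    stop_input("unknown gene_id in target_genes")
  fams <- unique(tx$family_id[tx$gene_id %in% target_genes])
  drop <- tx$family_id %in% fams & !(tx$gene_id %in% target_genes)
  subset_annotation(full, tx$transcript_id[!drop],
                    label = paste0(full$label, "_noparalogs"))
}

#' Pre-clinicalize a reference annotation to a species profile
#'
#' Restricts the reference to the profile's one-to-one ortholog genes at
#' full transcript depth (`ortholog_full`), then draws `reps` reduced
#' annotations in which every gene keeps exactly its species-level
#' transcript count: sampling is without replacement within a replicate and
#' independent across replicates.
#'
#' @param full reference [annotation()]
#' @param profile a [species_profile()]; genes missing from
#'   `per_gene_transcript_count` keep their full transcript complement
#' @param reps number of reduced annotations (default 100)
#' @param seed integer seed
#' @return list with elements `ortholog_full` (annotation) and `reduced`
#'   (named list of annotations, labels `preclin_<name>_rep<k>`)
#' @export
preclinicalize <- function(full, profile, reps = 100L, seed = 1L) {
  if (!inherits(profile, "species_profile"))
    stop_input("profile must be a species_profile")
  tx <- full$transcripts
  if (!all(profile$ortholog_genes %in% tx$gene_id))
    stop_input("profile ortholog genes absent from the reference")
  keep <- tx$gene_id %in% profile$ortholog_genes
  orth <- subset_annotation(full, tx$transcript_id[keep],
                            label = sprintf("ortholog_full_%s", profile$name))
  otx <- orth$transcripts
  full_cnt <- n_transcripts_per_gene(orth)
  cnt <- full_cnt
  has <- intersect(names(profile$per_gene_transcript_count), names(cnt))
  cnt[has] <- profile$per_gene_transcript_count[has]
  if (any(cnt > full_cnt))
    stop_input("profile demands more transcripts than the reference has")
  by_gene <- split(otx$transcript_id, otx$gene_id)
  reduced <- vector("list", reps)
  labels <- sprintf("preclin_%s_rep%03d", profile$name, seq_len(reps))
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      sel <- unlist(lapply(names(by_gene), function(g) {
        pool <- by_gene[[g]]
        k <- cnt[[g]]
        if (k >= length(pool)) pool else pool[sample.int(length(pool), k)]
      }), use.names = FALSE)
      reduced[[r]] <- subset_annotation(orth, sel, label = labels[r])
    }
  })
  names(reduced) <- labels
  list(ortholog_full = orth, reduced = reduced)
}

#' Vary gene lengths to emulate historical annotation drift
#'
#' `padded` mode appends an unexpressed padding block to every transcript of
#' a gene so that its length grows by the stated factor; padding blocks
#' never originate reads and never attract reads, so counts cannot rise
#' while the per-length rate x/y falls. `trimmed` mode removes whole blocks
#' from the transcript tail until the length is at or just above the target
#' (block granularity; at least one block is kept).
#'
#' @param full an [annotation()]
#' @param length_factor named numeric vector gene_id -> multiplier (> 0);
#'   genes not named keep their length
#' @param mode `"padded"` or `"trimmed"`
#' @return an [annotation()] labelled `<label>_lenvar`
#' @export
vary_gene_lengths <- function(full, length_factor,
                              mode = c("padded", "trimmed")) {
  mode <- match.arg(mode)
  if (any(length_factor <= 0)) stop_input("multipliers must be > 0")
  if (!all(names(length_factor) %in% full$transcripts$gene_id))
    stop_input("length_factor names genes absent from the annotation")
  tx <- full$transcripts
  bl <- full$blocks
  blen <- setNames(bl$length, bl$block_id)
  new_blocks <- list()
  for (i in seq_len(nrow(tx))) {
    g <- tx$gene_id[i]
    if (!g %in% names(length_factor)) next
    fac <- length_factor[[g]]
    if (fac == 1) next
    if (mode == "padded") {
      if (fac < 1) stop_input("padded mode requires multipliers >= 1")
      padlen <- round_half_up((fac - 1) * tx$length[i])
      if (padlen < 1L) next
      pid <- sprintf("PAD_%s", tx$transcript_id[i])
      new_blocks[[pid]] <- padlen
      tx$blocks[[i]] <- c(tx$blocks[[i]], pid)
      tx$length[i] <- tx$length[i] + padlen
    } else {
      target <- round_half_up(fac * tx$length[i])
      if (target < 1L) stop_input("cannot trim transcript ",
                                  tx$transcript_id[i], " below 1 nt")
      b <- tx$blocks[[i]]
      while (length(b) > 1L && tx$length[i] - blen[[b[length(b)]]] >= target) {
        tx$length[i] <- tx$length[i] - blen[[b[length(b)]]]
        b <- b[-length(b)]
      }
      tx$blocks[[i]] <- b
    }
  }
  if (length(new_blocks)) {
    bl <- rbind(bl, data.frame(block_id = names(new_blocks),
                               length = as.integer(unlist(new_blocks)),
                               pad = TRUE, stringsAsFactors = FALSE))
  } else if (mode == "trimmed") {
    used <- unique(unlist(tx$blocks, use.names = FALSE))
    bl <- bl[bl$block_id %in% used, , drop = FALSE]
  }
  annotation(tx, bl, label = paste0(full$label, "_lenvar"),
             version_tag = full$version_tag, validate = FALSE)
}
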