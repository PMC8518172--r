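# The synthetic transcriptome forge. Genes are built from abstract sequence
# blocks; paralog families are modelled by letting member genes share a set
# of family blocks covering a configurable fraction of each member's
# backbone length. Isoforms of one gene always contain the gene core block,
# so same-gene transcripts compete for reads drawn from shared blocks.

#' Paralog family specification
#'
#' @param fraction fraction of genes grouped into paralog families
#' @param size_range integer range of family sizes (inclusive)
#' @param shared_frac_range range of the fraction of a member gene's backbone
#'   length made of family-shared blocks (mappable homology)
#' @return a list of class `family_spec`
#' @export
family_spec <- function(fraction = 0.2, size_range = c(2L, 6L),
                        shared_frac_range = c(0.3, 0.7)) {
  if (fraction < 0 || fraction > 1)
    stop_config("family fraction must be in [0, 1]")
  if (length(size_range) != 2L || size_range[1] < 2L ||
      size_range[2] < size_range[1])
    stop_config("family size_range must be an increasing pair with min >= 2")
  if (any(shared_frac_range <= 0) || any(shared_frac_range >= 1) ||
      shared_frac_range[2] < shared_frac_range[1])
    stop_config("shared_frac_range must lie inside (0, 1)")
  structure(list(fraction = fraction, size_range = as.integer(size_range),
                 shared_frac_range = shared_frac_range),
            class = "family_spec")
}

#' Forge a synthetic multi-isoform transcriptome
#'
#' Builds an [annotation()] with `n_genes` genes. Each gene receives an
#' isoform count from `isoform_dist` and a backbone length from
#' `length_dist`; the backbone is split into blocks and every further
#' isoform is the gene core block plus a random block subset. A fraction of
#' genes (per `family_spec`) is grouped into paralog families whose members
#' share family blocks covering a stated fraction of their backbone length.
#'
#' @param n_genes number of genes (>= 1)
#' @param isoform_dist [dist_spec] for isoform counts per gene
#'   (default zero-truncated NB with mean 7, the human-like depth)
#' @param fam [family_spec()] controlling paralog families
#' @param length_dist [dist_spec] for backbone transcript length (nt)
#' @param seed integer seed; the result is bit-reproducible given the seed
#' @return an [annotation()] labelled `"full"`
#' @examples
#' ann <- forge_transcriptome(20, seed = 1)
#' ann
#' @export
forge_transcriptome <- function(n_genes,
                                isoform_dist = dist_ztnb(7, 2),
                                fam = family_spec(),
                                length_dist = dist_lognormal(log(2500), 0.6),
                                seed = 1L) {
  if (n_genes < 1L) stop_config("n_genes must be >= 1")
  if (!inherits(isoform_dist, "dist_spec") || !inherits(length_dist, "dist_spec"))
    stop_config("isoform_dist and length_dist must be dist_spec objects")
  if (!inherits(fam, "family_spec")) stop_config("fam must be a family_spec")
  withr::with_seed(seed, forge_impl(n_genes, isoform_dist, fam, length_dist))
}

forge_impl <- function(n_genes, isoform_dist, fam, length_dist) {
  gid <- sprintf("G%04d", seq_len(n_genes))
  n_iso <- pmax(1L, as.integer(draw_dist(isoform_dist, n_genes)))

  # family assignment: shuffle genes, greedily cut the first fraction into
  # families of random size; the rest are singleton families
  family_of <- setNames(gid, gid)          # default: own singleton family
  shared_frac <- setNames(rep(0, n_genes), gid)
  fam_members <- list()
  n_in_fam <- round_half_up(fam$fraction * n_genes)
  if (n_in_fam >= 2L) {
    pool <- sample(gid, n_in_fam)
    fi <- 0L
    while (length(pool) >= 2L) {
      fi <- fi + 1L
      sz <- min(length(pool),
                sample(seq(fam$size_range[1], fam$size_range[2]), 1L))
      mem <- pool[seq_len(sz)]
      pool <- pool[-seq_len(sz)]
      fname <- sprintf("FAM%03d", fi)
      family_of[mem] <- fname
      f <- runif(1, fam$shared_frac_range[1], fam$shared_frac_range[2])
      shared_frac[mem] <- f
      fam_members[[fname]] <- mem
    }
  }

  blocks_id <- character(); blocks_len <- integer()
  tx_rows <- vector("list", n_genes)

  # family-shared blocks, sized from a family backbone length draw
  fam_shared <- list()
  for (fname in names(fam_members)) {
    f <- shared_frac[fam_members[[fname]][1]]
    L <- max(200, draw_dist(length_dist, 1))
    shared_len <- max(2L, round_half_up(f * L))
    nsh <- sample(2:4, 1L)
    w <- rexp(nsh); w <- w / sum(w)
    bl <- pmax(1L, round_half_up(w * shared_len))
    ids <- sprintf("%s_S%02d", fname, seq_len(nsh))
    blocks_id <- c(blocks_id, ids); blocks_len <- c(blocks_len, bl)
    fam_shared[[fname]] <- ids
  }
  blen <- setNames(blocks_len, blocks_id)

  for (i in seq_len(n_genes)) {
    g <- gid[i]
    fname <- family_of[g]
    shared_ids <- if (!is.null(fam_shared[[fname]])) fam_shared[[fname]] else character()
    shared_len <- sum(blen[shared_ids])
    if (length(shared_ids)) {
      # private length chosen so shared/backbone equals the family's stated
      # sharing fraction exactly (up to block rounding)
      f <- shared_frac[g]
      priv_len <- max(3L, round_half_up(shared_len * (1 - f) / f))
    } else {
      priv_len <- max(3L, round_half_up(draw_dist(length_dist, 1)))
    }
    npr <- max(3L, min(n_iso[i] + 2L, 10L))
    w <- rexp(npr); w <- w / sum(w)
    pl <- pmax(1L, round_half_up(w * priv_len))
    pids <- sprintf("%s_B%02d", g, seq_len(npr))
    blocks_id <- c(blocks_id, pids); blocks_len <- c(blocks_len, pl)
    blen[pids] <- pl

    all_blocks <- c(shared_ids, pids)
    core <- all_blocks[1]                 # first shared block, else first private
    iso_blocks <- vector("list", n_iso[i])
    iso_blocks[[1]] <- all_blocks         # backbone isoform carries everything
    if (n_iso[i] > 1L) {
      others <- setdiff(all_blocks, core)
      for (j in 2:n_iso[i]) {
        keep <- others[runif(length(others)) < 0.6]
        iso_blocks[[j]] <- c(core, keep)
      }
    }
    tx_rows[[i]] <- data.frame(
      transcript_id = sprintf("%s_T%02d", g, seq_len(n_iso[i])),
      gene_id = g, family_id = unname(fname),
      length = vapply(iso_blocks, function(b) sum(blen[b]), numeric(1)),
      stringsAsFactors = FALSE)
    tx_rows[[i]]$blocks <- iso_blocks
  }

  tx <- do.call(rbind, tx_rows)
  bl <- data.frame(block_id = blocks_id, length = as.integer(blocks_len),
                   pad = FALSE, stringsAsFactors = FALSE)
  annotation(tx, bl, label = "full", version_tag = "forge-1", validate = FALSE)
}

#' Simulate ground-truth expression over an annotation
#'
#' Gene-level weights are drawn log-uniformly over `dynamic_range_log10`
#' decades (with the extreme two genes pinned to the range ends so the
#' realized span equals the request exactly); isoform proportions within a
#' gene are symmetric Dirichlet(1). The default range is chosen so that, on
#' the default 500-gene forge, full-annotation gene tpm populates log10 bins
#' from 0.5 to 4.5.
#'
#' @param ann an [annotation()]
#' @param dynamic_range_log10 decades spanned by gene abundance (> 0)
#' @param seed integer seed
#' @return an [expression_truth()]
#' @export
simulate_expression <- function(ann, dynamic_range_log10 = 4.5, seed = 1L) {
  if (!inherits(ann, "annotation")) stop_input("ann must be an annotation")
  if (nrow(ann$transcripts) == 0L) stop_input("annotation is empty")
  if (dynamic_range_log10 <= 0) stop_config("dynamic_range_log10 must be > 0")
  withr::with_seed(seed, {
    genes <- gene_ids(ann)
    ng <- length(genes)
    expo <- runif(ng, 0, dynamic_range_log10)
    if (ng >= 2L) {
      pin <- sample(ng, 2L)      # pin realized span to the requested range
      expo[pin[1]] <- 0
      expo[pin[2]] <- dynamic_range_log10
    }
    gw <- setNames(10^expo, genes)
    tx <- ann$transcripts
    iso_w <- rexp(nrow(tx))
    iso_w <- iso_w / ave(iso_w, tx$gene_id, FUN = sum)
    theta <- gw[tx$gene_id] * iso_w
    theta <- theta / sum(theta)
    expression_truth(setNames(as.numeric(theta), tx$transcript_id))
  })
}

#' Simulate an abstract read set
#'
#' Each read picks an origin transcript with probability proportional to
#' `theta_i * length_i` (longer transcripts shed more fragments, matching
#' the per-length rate in the tpm definition), then a position uniform along
#' the transcript's non-padding length; the covered block is recorded. The
#' read's compatibility set against any annotation is every transcript
#' containing that block.
#'
#' @param truth an [expression_truth()]; names must be a subset of `ann`'s
#'   transcript ids
#' @param ann the generating [annotation()]
#' @param n_reads number of reads (>= 0)
#' @param seed integer seed
#' @return a [read_set()]
#' @export
simulate_reads <- function(truth, ann, n_reads, seed = 1L) {
  if (!inherits(truth, "expression_truth")) stop_input("truth must be an expression_truth")
  if (!inherits(ann, "annotation")) stop_input("ann must be an annotation")
  if (n_reads < 0) stop_input("n_reads must be >= 0")
  if (!all(names(truth$theta) %in% tx_ids(ann)))
    stop_input("truth names transcripts absent from the annotation")
  if (n_reads == 0L) return(read_set())
  withr::with_seed(seed, {
    blen <- setNames(ann$blocks$length, ann$blocks$block_id)
    pad <- setNames(ann$blocks$pad, ann$blocks$block_id)
    tx <- ann$transcripts
    m <- match(names(truth$theta), tx$transcript_id)
    nonpad_len <- vapply(tx$blocks[m], function(b) sum(blen[b][!pad[b]]),
                         numeric(1))
    w <- truth$theta * nonpad_len
    if (sum(w) <= 0) stop_input("no expressed transcript with mappable length")
    origin_i <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    block <- character(n_reads)
    for (oi in sort(unique(origin_i))) {
      rows <- which(origin_i == oi)
      b <- tx$blocks[[m[oi]]]
      b <- b[!pad[b]]
      if (length(b) == 1L) block[rows] <- b
      else block[rows] <- b[sample.int(length(b), length(rows),
                                       replace = TRUE, prob = blen[b])]
    }
    read_set(origin = names(truth$theta)[origin_i], block = block)
  })
}

#' Thin a read set to emulate lower sequencing depth
#'
#' @param reads a [read_set()]
#' @param keep_prob probability in `[0, 1]` of retaining each read
#'   independently
#' @param seed integer seed
#' @return a [read_set()]
#' @export
thin_reads <- function(reads, keep_prob, seed = 1L) {
  if (keep_prob < 0 || keep_prob > 1) stop_input("keep_prob must be in [0, 1]")
  if (nrow(reads) == 0L || keep_prob == 1) return(reads)
  if (keep_prob == 0) return(read_set())
  withr::with_seed(seed, {
    keep <- runif(nrow(reads)) < keep_prob
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Derive a species annotation profile from a reference annotation
#'
#' Emulates a pre-clinical species' shallower annotation: each reference
#' gene's transcript count is scaled towards `target_mean` isoforms per gene
#' (zero-truncated NB draw capped at the gene's own count), and a random
#' fraction of genes is declared one-to-one orthologous.
#'
#' @param ann reference [annotation()]
#' @param name species name
#' @param target_mean target mean transcripts per gene (e.g. 1.5-5 for
#'   pre-clinical species versus ~7 for the human-like reference)
#' @param ortholog_fraction fraction of reference genes with an ortholog
#' @param seed integer seed
#' @return a [species_profile()]
#' @export
forge_species_profile <- function(ann, name, target_mean = 2,
                                  ortholog_fraction = 0.8, seed = 1L) {
  ref_cnt <- n_transcripts_per_gene(ann)
  withr::with_seed(seed, {
    draw <- if (target_mean > 1)
      as.integer(draw_dist(dist_ztnb(target_mean, 2), length(ref_cnt)))
    else rep(1L, length(ref_cnt))
    cnt <- pmin(ref_cnt, pmax(1L, draw))
    orth <- sample(names(ref_cnt),
                   max(1L, round_half_up(ortholog_fraction * length(ref_cnt))))
  })
  species_profile(name, setNames(cnt, names(ref_cnt)), sort(orth),
                  reference = ann)
}
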