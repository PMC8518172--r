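# Standard-format I/O and the config-driven experiment runner. All tables
# are plain TSV; annotations use a dialect that encodes each block as
# "id:length" (":pad" suffix for padding blocks) so that a written
# annotation round-trips bit-exactly.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Annotation TSV round trip
#'
#' Columns: transcript_id, gene_id, family_id, length, block_ids (semicolon
#' separated `id:length[:pad]` tokens).
#'
#' @param ann an [annotation()]
#' @param path file path
#' @return `write_annotation_tsv()` the path, invisibly;
#'   `read_annotation_tsv()` the reconstructed annotation
#' @export
write_annotation_tsv <- function(ann, path) {
  blen <- setNames(ann$blocks$length, ann$blocks$block_id)
  pad <- setNames(ann$blocks$pad, ann$blocks$block_id)
  enc <- vapply(ann$transcripts$blocks, function(b)
    paste(sprintf("%s:%d%s", b, blen[b], ifelse(pad[b], ":pad", "")),
          collapse = ";"), character(1))
  df <- ann$transcripts[, c("transcript_id", "gene_id", "family_id", "length")]
  df$block_ids <- enc
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# annotation label=%s version=%s", ann$label,
                     ann$version_tag), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  label <- sub(".*label=(\\S+).*", "\\1", hdr)
  version <- sub(".*version=(\\S+).*", "\\1", hdr)
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "family_id", "length", "block_ids")
  if (!all(need %in% names(df)))
    stop_input("annotation TSV missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  toks <- strsplit(df$block_ids, ";", fixed = TRUE)
  bid <- character(); blen <- integer(); bpad <- logical()
  blocks_col <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    parts <- strsplit(toks[[i]], ":", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    lens <- as.integer(vapply(parts, `[`, character(1), 2L))
    pads <- vapply(parts, function(p) length(p) > 2L && p[3] == "pad",
                   logical(1))
    if (anyNA(lens))
      stop_input("malformed block token at row ", i, " of ", path)
    new <- !ids %in% bid
    bid <- c(bid, ids[new]); blen <- c(blen, lens[new])
    bpad <- c(bpad, pads[new])
    blocks_col[[i]] <- ids
  }
  tx <- df[, c("transcript_id", "gene_id", "family_id", "length")]
  tx$blocks <- blocks_col
  annotation(tx, data.frame(block_id = bid, length = blen, pad = bpad,
                            stringsAsFactors = FALSE),
             label = label, version_tag = version)
}

#' Quantification table round trip
#'
#' Fixed columns: `transcript_id`, `reads_mapped`, `length`, `tpm` (gene
#' tables: `gene_id`, `reads_mapped`, `tpm`, `represented_length_fraction`).
#' Malformed rows (negative counts, non-positive lengths) are rejected with
#' their row index; the denominator S and mapped-read total are recomputed
#' on read.
#'
#' @param quant a `sample_quant`
#' @param path file path
#' @return the path / the reconstructed `sample_quant`
#' @export
write_quant_tsv <- function(quant, path) {
  df <- data.frame(transcript_id = quant$transcript_id,
                   reads_mapped = quant$reads, length = quant$length,
                   tpm = quant$tpm, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_quant_tsv
#' @export
read_quant_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("transcript_id", "reads_mapped", "length", "tpm")
  if (!all(need %in% names(df)))
    stop_input("quant TSV missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(df$reads_mapped < 0 | !is.finite(df$reads_mapped))
  if (length(bad))
    stop_input("negative or non-finite read count at row ", bad[1])
  bad <- which(df$length <= 0)
  if (length(bad)) stop_input("non-positive length at row ", bad[1])
  compute_tpm(setNames(df$reads_mapped, df$transcript_id), df$length)
}

#' Gene-level quantification table round trip
#' @param gq a `gene_quant`
#' @param path file path
#' @param S,label denominator and label to re-attach on read
#' @return the path / a `gene_quant`
#' @export
write_gene_quant_tsv <- function(gq, path) {
  df <- data.frame(gene_id = gq$gene_id, reads_mapped = gq$reads,
                   tpm = gq$tpm,
                   represented_length_fraction = gq$represented_length_fraction,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_gene_quant_tsv
#' @export
read_gene_quant_tsv <- function(path, S = NA_real_, label = "sample") {
  df <- read_tsv(path)
  bad <- which(df$reads_mapped < 0)
  if (length(bad)) stop_input("negative read count at row ", bad[1])
  structure(data.frame(gene_id = df$gene_id, reads = df$reads_mapped,
                       tpm = df$tpm,
                       represented_length_fraction = df$represented_length_fraction,
                       stringsAsFactors = FALSE),
            S = S, n_mapped = sum(df$reads_mapped), label = label,
            class = c("gene_quant", "data.frame"))
}

#' Expression-truth and read-set TSV round trips
#' @param truth an [expression_truth()]; `reads` a [read_set()]
#' @param path file path
#' @return the path / the reconstructed object
#' @name truth-io
NULL

#' @rdname truth-io
#' @export
write_truth_tsv <- function(truth, path) {
  write_tsv(data.frame(transcript_id = names(truth$theta),
                       theta = sprintf("%.17g", truth$theta),
                       stringsAsFactors = FALSE), path)
}

#' @rdname truth-io
#' @export
read_truth_tsv <- function(path) {
  df <- read_tsv(path)
  expression_truth(setNames(as.numeric(df$theta), df$transcript_id),
                   normalize = TRUE)
}

#' @rdname truth-io
#' @param reads a [read_set()]
#' @export
write_reads_tsv <- function(reads, path) {
  write_tsv(as.data.frame(reads), path)
}

#' @rdname truth-io
#' @export
read_reads_tsv <- function(path) {
  df <- read_tsv(path)
  read_set(origin = df$origin, block = df$block)
}

#' Ortholog map TSV round trip
#' @param map data.frame with columns `gene_ref`, `gene_other`
#' @param path file path
#' @return the path / the map
#' @export
write_ortholog_tsv <- function(map, path) write_tsv(map, path)

#' @rdname write_ortholog_tsv
#' @export
read_ortholog_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_ref", "gene_other") %in% names(df)))
    stop_input("ortholog TSV needs columns gene_ref, gene_other")
  if (anyDuplicated(df$gene_ref) || anyDuplicated(df$gene_other))
    stop_input("ortholog map must be one-to-one")
  df
}

#' Export a forged annotation as FASTA (interoperability demo)
#'
#' Every transcript gets a deterministic synthetic sequence assembled from
#' per-block pseudo-random nucleotides, so shared blocks share sequence.
#'
#' @param ann an [annotation()]
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
write_annotation_fasta <- function(ann, path) {
  blen <- setNames(ann$blocks$length, ann$blocks$block_id)
  seq_of_block <- function(bid) {
    s <- derive_seed(0L, paste0("fasta/", bid))
    withr::with_seed(s, paste(sample(c("A", "C", "G", "T"), blen[[bid]],
                                     replace = TRUE), collapse = ""))
  }
  cache <- new.env(parent = emptyenv())
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ann$transcripts))) {
    bids <- ann$transcripts$blocks[[i]]
    seqs <- vapply(bids, function(b) {
      if (is.null(cache[[b]])) cache[[b]] <- seq_of_block(b)
      cache[[b]]
    }, character(1))
    writeLines(c(sprintf(">%s gene=%s", ann$transcripts$transcript_id[i],
                         ann$transcripts$gene_id[i]),
                 paste(seqs, collapse = "")), con)
  }
  invisible(path)
}

#' Read ids and sequence lengths from a FASTA file
#' @param path FASTA path
#' @return data.frame (transcript_id, length)
#' @export
read_fasta_lengths <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  lens <- tapply(nchar(lines[!hdr]), grp[!hdr], sum)
  data.frame(transcript_id = ids, length = as.integer(lens),
             stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' A serializable bundle of every tunable the pipeline uses, with one
#' explicit top-level seed from which all stage seeds are derived. Two
#' scales are named: `desk` (500 genes, 10 fractions x 20 reps, 1e5 reads;
#' minutes on one CPU) and `paper` (the full 1-99% x 100 protocol).
#'
#' @param seed top-level integer seed
#' @param scale `"desk"` or `"paper"`
#' @param n_genes genes to forge
#' @param n_reads reads to simulate
#' @param isoform_mean,isoform_size zero-truncated NB isoform-count
#'   parameters
#' @param family_fraction,family_size_range,family_shared_range paralog
#'   family parameters (see [family_spec()])
#' @param length_meanlog,length_sdlog lognormal backbone-length parameters
#' @param dynamic_range_log10 expression dynamic range
#' @param fractions,reps_per_fraction sweep grid (`NULL` = scale default)
#' @param n_control_bins control-gene bins for [stratified_select_genes()]
#' @param tpm_floor,logratio_trim,abs_expr_trim normalization parameters
#' @param inflation_threshold,n_perm stats parameters
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(seed = 1L, scale = c("desk", "paper"),
                              n_genes = 500L, n_reads = 1e5,
                              isoform_mean = 7, isoform_size = 2,
                              family_fraction = 0.2,
                              family_size_range = c(2L, 6L),
                              family_shared_range = c(0.3, 0.7),
                              length_meanlog = log(2500), length_sdlog = 0.6,
                              dynamic_range_log10 = 4.5,
                              fractions = NULL, reps_per_fraction = NULL,
                              n_control_bins = 10L,
                              tpm_floor = 1, logratio_trim = 0.30,
                              abs_expr_trim = 0.05,
                              inflation_threshold = 0.1, n_perm = 1000L) {
  scale <- match.arg(scale)
  if (is.null(fractions))
    fractions <- if (scale == "paper") 1:99 else
      c(10, 20, 30, 40, 50, 60, 70, 80, 90, 99)
  if (is.null(reps_per_fraction))
    reps_per_fraction <- if (scale == "paper") 100L else 20L
  structure(list(seed = as.integer(seed), scale = scale,
                 n_genes = as.integer(n_genes), n_reads = as.integer(n_reads),
                 isoform_mean = isoform_mean, isoform_size = isoform_size,
                 family_fraction = family_fraction,
                 family_size_range = as.integer(family_size_range),
                 family_shared_range = family_shared_range,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 dynamic_range_log10 = dynamic_range_log10,
                 fractions = as.numeric(fractions),
                 reps_per_fraction = as.integer(reps_per_fraction),
                 n_control_bins = as.integer(n_control_bins),
                 tpm_floor = tpm_floor, logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim,
                 inflation_threshold = inflation_threshold,
                 n_perm = as.integer(n_perm)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an `experiment_config`
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, x[setdiff(names(x), "scale")] |>
            c(list(scale = x$scale)))
}

#' @rdname experiment_config
#' @export
config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

forge_from_config <- function(config) {
  forge_transcriptome(
    config$n_genes,
    isoform_dist = dist_ztnb(config$isoform_mean, config$isoform_size),
    fam = family_spec(config$family_fraction, config$family_size_range,
                      config$family_shared_range),
    length_dist = dist_lognormal(config$length_meanlog, config$length_sdlog),
    seed = derive_seed(config$seed, "forge"))
}

#' Run a named experiment end to end
#'
#' Orchestrates the pipeline stages into the four annotation experiments
#' plus the correction workflow, writing tables, a manifest and a
#' machine-readable `summary.json` (stamped with the config hash and seed)
#' into `out_dir`. Identical config and seed produce byte-identical tables.
#'
#' @param config an [experiment_config()]
#' @param which one of `"sweep"`, `"paralogs"`, `"preclinicalize"`,
#'   `"history"`, `"correction"`
#' @param out_dir output directory (created if needed)
#' @return the summary list, invisibly
#' @export
run_experiment <- function(config,
                           which = c("sweep", "paralogs", "preclinicalize",
                                     "history", "correction"),
                           out_dir) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed,
                scale = config$scale, experiment = which)
  full <- forge_from_config(config)
  truth <- simulate_expression(full, config$dynamic_range_log10,
                               seed = derive_seed(config$seed, "truth"))
  reads <- simulate_reads(truth, full, config$n_reads,
                          seed = derive_seed(config$seed, "reads"))
  write_annotation_tsv(full, file.path(out_dir, "annotation_full.tsv"))
  full_q <- quantify_sample(reads, full)
  full_g <- summarize_to_gene(full_q, full, full)
  write_gene_quant_tsv(full_g, file.path(out_dir, "gene_quant_full.tsv"))

  summary <- switch(which,
    sweep = , paralogs = {
      ctrl <- stratified_select_genes(full_g, config$n_control_bins,
                                      seed = derive_seed(config$seed, "ctrl"))
      base <- full
      if (which == "paralogs") base <- remove_paralogs(full, ctrl)
      keep <- base$transcripts$transcript_id[base$transcripts$gene_id %in% ctrl]
      scheme <- sweep_scheme(config$fractions, config$reps_per_fraction,
                             keep_set = keep,
                             seed = derive_seed(config$seed, "sweep"))
      anns <- subsample_sweep(base, scheme)
      gq <- lapply(anns, function(a)
        summarize_to_gene(quantify_sample(reads, a), a, full))
      attr(gq, "manifest") <- attr(anns, "manifest")
      res <- build_sweep_result(gq, full_g, ctrl)
      write_tsv(attr(anns, "manifest"), file.path(out_dir, "sweep_manifest.tsv"))
      write_tsv(as.data.frame(res), file.path(out_dir, "sweep_result.tsv"))
      sig <- inflation_significance(res)
      write_tsv(as.data.frame(sig), file.path(out_dir, "significance.tsv"))
      diag <- denominator_diagnostic(gq, full_g, ctrl)
      write_tsv(diag, file.path(out_dir, "denominator_diagnostic.tsv"))
      mean_diff <- tapply(res$log10_tpm_diff[!res$dropout],
                          res$fraction[!res$dropout], mean)
      c(stamp, list(n_annotations = length(anns),
                    control_genes = ctrl,
                    mean_log10_tpm_diff_by_fraction = as.list(mean_diff),
                    n_significant = sum(sig$call)))
    },
    preclinicalize = {
      species_means <- c(cyno = 5, dog = 2.5, rat = 2, mouse = 3)
      out_n <- 0L; flagged <- list()
      for (sp in names(species_means)) {
        prof <- forge_species_profile(full, sp, species_means[[sp]],
                                      seed = derive_seed(config$seed,
                                                         paste0("prof/", sp)))
        pc <- preclinicalize(full, prof, reps = config$reps_per_fraction,
                             seed = derive_seed(config$seed,
                                                paste0("preclin/", sp)))
        oq <- summarize_to_gene(quantify_sample(reads, pc$ortholog_full),
                                pc$ortholog_full, full)
        gq <- lapply(pc$reduced, function(a)
          summarize_to_gene(quantify_sample(reads, a), a, full))
        ch <- characterize_inflated_genes(gq, oq, n_perm = config$n_perm,
                                          seed = derive_seed(config$seed,
                                                             paste0("perm/", sp)),
                                          threshold = config$inflation_threshold)
        write_tsv(ch$per_gene,
                  file.path(out_dir, sprintf("preclin_%s_per_gene.tsv", sp)))
        out_n <- out_n + length(pc$reduced)
        flagged[[sp]] <- list(flagged = ch$flagged,
                              percentile = ch$percentile)
      }
      c(stamp, list(n_annotations = out_n, species = flagged))
    },
    history = {
      genes <- gene_ids(full)
      fac <- setNames(rep(1, length(genes)), genes)
      drift <- withr::with_seed(derive_seed(config$seed, "history"),
                                sample(genes, max(1L, length(genes) %/% 10L)))
      fac[drift] <- 2
      hist_ann <- vary_gene_lengths(full, fac, mode = "padded")
      hq <- quantify_sample(reads, hist_ann)
      hg <- summarize_to_gene(hq, hist_ann, hist_ann)
      write_gene_quant_tsv(hg, file.path(out_dir, "gene_quant_history.tsv"))
      m <- match(drift, hg$gene_id)
      f <- match(drift, full_g$gene_id)
      c(stamp, list(n_drift_genes = length(drift),
                    mean_log10_tpm_shift =
                      mean(log10(hg$tpm[m]) - log10(full_g$tpm[f]))))
    },
    correction = {
      thin <- thin_reads(reads, 0.2, seed = derive_seed(config$seed, "thin"))
      tq <- summarize_to_gene(quantify_sample(thin, full), full, full)
      hum <- matrix(full_g$tpm, dimnames = list(full_g$gene_id, "human_1"))
      spc <- matrix(tq$tpm, dimnames = list(tq$gene_id, "species_1"))
      nx <- normalize_cross_species(hum, spc, tpm_floor = config$tpm_floor,
                                    logratio_trim = config$logratio_trim,
                                    abs_expr_trim = config$abs_expr_trim)
      write_tsv(nx$diagnostics, file.path(out_dir, "correction_diagnostics.tsv"))
      write_tsv(nx$factors, file.path(out_dir, "correction_factors.tsv"))
      d <- nx$diagnostics
      c(stamp, list(
        median_pre = d$median_log10_diff[d$stage == "pre"],
        median_post = d$median_log10_diff[d$stage == "post"]))
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
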