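# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero (round-half-up for positive input)
#'
#' Base R `round()` rounds half to even; subsample sizes use the conventional
#' round-half-up so that e.g. 2.5% of a 100-transcript pool is 3 transcripts.
#' @param x numeric vector (non-negative in all internal uses)
#' @return integer vector
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

stop_config <- function(...) {
  stop(structure(class = c("tpmdepth_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("tpmdepth_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# FNV-1a 32-bit hash of a character scalar; used to stamp output tables with
# the configuration that produced them without pulling in a digest dependency.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h a double in [0, 2^32)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact
    # in double precision.
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a child seed from a base seed and a stream label, kept below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  strtoi(substr(fnv1a32(paste0(seed, "/", stream)), 1, 7), base = 16L)
}
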