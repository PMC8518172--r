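# Distribution specifications used by the transcriptome forge. A spec is a
# small tagged list so that configurations serialize cleanly to JSON.

#' Distribution specifications for the transcriptome forge
#'
#' `dist_constant()` always returns `value`. `dist_ztnb()` is a zero-truncated
#' negative binomial whose *truncated* mean is calibrated to `mean` (the
#' underlying NB mean is solved numerically), used for isoform counts per
#' gene. `dist_lognormal()` draws lognormal lengths in nucleotides.
#' `dist_uniform()` draws uniformly on `[min, max]`.
#'
#' @param value constant value returned by every draw
#' @param mean target mean of the zero-truncated distribution (must be > 1)
#' @param size NB dispersion parameter (larger = closer to Poisson)
#' @param meanlog,sdlog lognormal parameters on the natural-log scale
#' @param min,max uniform bounds
#' @return an object of class `dist_spec`
#' @examples
#' draw_dist(dist_constant(1), 5)
#' mean(draw_dist(dist_ztnb(7, 2), 1e4))
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_constant <- function(value) {
  if (!is.finite(value)) stop_config("dist_constant: value must be finite")
  structure(list(type = "constant", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_ztnb <- function(mean, size = 2) {
  if (!is.finite(mean) || mean <= 1)
    stop_config("dist_ztnb: truncated mean must exceed 1")
  if (!is.finite(size) || size <= 0)
    stop_config("dist_ztnb: size must be positive")
  structure(list(type = "ztnb", mean = mean, size = size), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog < 0)
    stop_config("dist_lognormal: invalid parameters")
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  if (!is.finite(min) || !is.finite(max) || max < min)
    stop_config("dist_uniform: invalid bounds")
  structure(list(type = "uniform", min = min, max = max), class = "dist_spec")
}

# Solve for the untruncated NB mean mu such that E[X | X > 0] = target.
ztnb_mu <- function(target_mean, size) {
  f <- function(mu) mu / (1 - dnbinom(0, mu = mu, size = size)) - target_mean
  stats::uniroot(f, lower = 1e-8, upper = target_mean, tol = 1e-10)$root
}

#' Draw from a distribution specification
#'
#' @param spec a `dist_spec`
#' @param n number of draws
#' @return numeric vector of length `n` (integer-valued for count specs)
#' @export
draw_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) stop_config("not a dist_spec")
  switch(spec$type,
    constant = rep(spec$value, n),
    ztnb = {
      mu <- ztnb_mu(spec$mean, spec$size)
      x <- rnbinom(n, mu = mu, size = spec$size)
      # redraw zeros (truncation); zero probability is modest for our means
      while (any(x == 0L)) {
        i <- which(x == 0L)
        x[i] <- rnbinom(length(i), mu = mu, size = spec$size)
      }
      x
    },
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    uniform = runif(n, spec$min, spec$max),
    stop_config("unknown distribution type: ", spec$type)
  )
}

#' @importFrom stats dnbinom
NULL
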