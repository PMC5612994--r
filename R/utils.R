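#' Fisher r-to-z transform
#'
#' @param r correlations in `[-1, 1]`. Values at exactly +/-1 are clipped to
#'   +/-(1 - 1e-7) with a warning, so the transform stays finite.
#' @return `atanh` of the (possibly clipped) input.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r))) stop("non-finite correlation values")
  if (any(r < -1 | r > 1)) stop("correlations must lie in [-1, 1]")
  clip <- abs(r) >= 1 - 1e-7
  if (any(clip)) {
    warning("correlations at +/-1 clipped to +/-(1 - 1e-7) before Fisher transform")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Inverse Fisher transform
#' @param z Fisher z values.
#' @export
fisher_inv <- function(z) tanh(z)

#' Average correlations on the Fisher z scale
#'
#' All averaging of correlation values in this package happens on the
#' variance-stabilized `atanh` scale and is mapped back with `tanh`.
#'
#' @param r numeric vector of correlations.
#' @return scalar, `tanh(mean(atanh(r)))`.
#' @export
fisher_average <- function(r) {
  if (length(r) == 0) stop("cannot Fisher-average an empty vector")
  fisher_inv(mean(fisher_z(r)))
}

# Deterministic derivation of per-stage seeds from one top-level seed.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
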