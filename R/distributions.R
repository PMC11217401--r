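#' Distribution primitives for parameter sampling
#'
#' The model's parameter distributions come in five families: `point`
#' (degenerate), `normal`, `truncated_normal` (normal truncated at zero),
#' `uniform`, and `triangular`. Truncated-normal and triangular variates are
#' generated by inverse-CDF transforms of uniforms so that a single uniform
#' stream per parameter fully determines the draw.
#'
#' @name distributions
#' @keywords internal
NULL

DIST_KINDS <- c("point", "normal", "truncated_normal", "uniform", "triangular")

#' Triangular distribution quantile function
#'
#' Inverse CDF of the triangular distribution with support `[min, max]` and
#' mode `mode`.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @param min,mode,max distribution parameters, `min <= mode <= max`.
#' @return numeric vector of quantiles.
#' @examples
#' qtriangular(0.5, 0, 1, 2)  # median of a symmetric triangular = mode
#' @export
qtriangular <- function(p, min, mode, max) {
  stopifnot(min <= mode, mode <= max)
  if (max == min) return(rep(min, length(p)))
  fc <- (mode - min) / (max - min)
  lower <- p < fc
  out <- numeric(length(p))
  out[lower] <- min + sqrt(p[lower] * (max - min) * (mode - min))
  out[!lower] <- max - sqrt((1 - p[!lower]) * (max - min) * (max - mode))
  out
}

#' Zero-truncated normal quantile function
#'
#' Quantiles of a normal distribution conditioned on being non-negative.
#' Used for physically non-negative parameters whose uncertainty is stated
#' as a standard deviation.
#'
#' @param p probabilities in `[0, 1]`.
#' @param mean,sd parameters of the parent normal.
#' @return non-negative quantiles.
#' @export
qtnorm0 <- function(p, mean, sd) {
  if (sd <= 0) return(rep(pmax(mean, 0), length(p)))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + p * (1 - p0), mean, sd)
}

# Deterministic, order-independent stream seed for one named parameter.
# A per-parameter seed derived from (global seed, parameter id) keeps each
# parameter's uniform stream fixed whether it is sampled alone (one-at-a-time
# sensitivity) or together with the rest of the registry.
param_stream_seed <- function(seed, id) {
  h <- 5381
  for (ch in utf8ToInt(id)) h <- (h * 33 + ch) %% 1987654321
  as.integer((h + as.numeric(seed) * 97003) %% 2147483629L)
}

# n uniforms from the parameter's private stream
param_uniforms <- function(seed, id, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(param_stream_seed(seed, id))
  stats::runif(n)
}

# Map uniforms through one ParameterSpec row's distribution
quantile_for_spec <- function(p, dist_kind, central, p1, p2, p3, truncated = TRUE) {
  switch(dist_kind,
    point = rep(central, length(p)),
    normal = if (isTRUE(truncated)) qtnorm0(p, central, p1)
             else stats::qnorm(p, central, p1),
    truncated_normal = qtnorm0(p, central, p1),
    uniform = p1 + p * (p2 - p1),
    triangular = qtriangular(p, p1, p2, p3),
    stop("unknown dist_kind: ", dist_kind)
  )
}
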