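#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from a single run seed. Each component
#' (parameter init, splits, negative sampling, corruption sampling, Bayesian
#' optimization, data generation) draws from its own named sub-stream so that
#' toggling one stage does not perturb the randomness of another.
#'
#' @param seed master integer seed.
#' @param name character sub-stream name, e.g. "init" or "splits".
#' @return an integer seed in [0, 2^31-1).
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# consistent stop() with a short prefix so errors are greppable
dti_stop <- function(...) stop(sprintf(...), call. = FALSE)

dti_warn <- function(...) warning(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) dti_stop("non-finite values in %s", what)
  invisible(x)
}

# row-wise scatter add: out[idx[e], ] += val[e, ] without a loop
rowsum_add <- function(base, idx, val) {
  if (length(idx) == 0L) return(base)
  agg <- rowsum(val, group = idx)
  rows <- as.integer(rownames(agg))
  base[rows, ] <- base[rows, , drop = FALSE] + agg
  base
}
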