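#' Derive a deterministic child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a short tag, so stages can be re-run in isolation yet remain
#' reproducible end-to-end.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the consumer (e.g. `"f2"`, `"perm"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483399 + 1)
}

# internal: stop with a consistent message for bad parameters
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
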