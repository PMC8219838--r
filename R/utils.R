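#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic operation in the pipeline takes an explicit seed derived
#' from a single master seed via this counter scheme, so that a whole
#' experiment is reproducible from one integer.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer counter (stage index, neuron index,
#'   trial block, ...).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  # multiplicative hash keeps distinct (master, counter) pairs distinct for
  # the small counters used here while staying inside 32-bit integer range
  as.integer((abs(master) * 7919 + counter * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lgnsnr <- function(msg, class) {
  stop(structure(class = c(class, "lgnsnr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
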