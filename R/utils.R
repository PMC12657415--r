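#' Derive a stage-specific seed from a master seed
#'
#' Sub-seeds for the individual stages of an experiment are derived
#' deterministically from a single master seed and a stage name, so that
#' adding a stage to a pipeline never reshuffles the randomness consumed by
#' earlier stages. The scheme is a simple polynomial rolling hash of the
#' stage name folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"split"`,
#'   `"subset:0.4"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# round-half-up to an integer; round() half-to-even would break the
# 0.01 * 13460 = 134.6 -> 135 convention only at exact halves, but we fix
# the convention explicitly anyway
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric logistic link, stable at extreme arguments
logistic <- function(x) stats::plogis(x)
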