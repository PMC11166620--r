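#' Derive a per-stage RNG seed from a master seed
#'
#' Deterministic integer mixing of the master seed with a stage name, kept
#' below 2^31 so results are reproducible across platforms.  Every stage
#' of a study derives its own stream from the master seed this way.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) * 48271 + h * 9973 + 1) %% 2147483587)
}
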