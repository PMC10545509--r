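#' Derive a child seed from a parent seed and a key
#'
#' Hierarchical seeding: every stochastic stage (cohort, listener, trial
#' noise) takes a seed derived deterministically from the run seed and a
#' stage key, so any stage is reproducible in isolation. The mix is a
#' simple multiplicative hash kept below 2^31 - 1.
#'
#' @param seed Parent integer seed.
#' @param ... Keys (strings or integers) identifying the child stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(k) else as.integer(k)
  }))
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (k in keys) h <- (h * 48271 + as.numeric(k) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}
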