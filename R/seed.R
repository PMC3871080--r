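#' Derive a deterministic child seed from a master seed
#'
#' Every stage of a simulated study draws from its own named random stream,
#' keyed by a master seed plus a sequence of tags (subject id, activity label,
#' device id, stage name, ...). Paired devices share the true-signal stream by
#' construction because the true-signal tag sequence omits the device id.
#'
#' The hash is a plain polynomial string hash modulo 2^31 - 1, so the result is
#' a valid 32-bit seed on every platform.
#'
#' @param master integer master seed.
#' @param ... tags naming the stream; coerced to character.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "bout", "S01", "walk_2.0")
child_seed <- function(master, ...) {
  tags <- vapply(list(...), function(t) paste(as.character(t), collapse = ","),
                 character(1))
  key <- paste(c(as.character(master), tags), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# run code under a temporary RNG state (global stream untouched)
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
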