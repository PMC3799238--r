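# Internal helpers shared across modules.

ms2s <- function(x) x / 1000

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages draw their seed from a master seed plus a named
#' substream, so modules can be regenerated independently and results do
#' not depend on execution order.
#'
#' @param master integer master seed.
#' @param name character stream name (e.g. `"lfp"`, `"units"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  # small polynomial string hash; kept well inside 32-bit integer range
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 1048573
  as.integer((abs(master) %% 1048573) * 2039 + h * 7 + 1) %% 2147483646L
}

# run `expr` under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# half-open interval membership [a, b)
in_window <- function(x, win) x >= win[1] & x < win[2]

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
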