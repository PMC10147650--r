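#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible 32-bit stream seed from a master seed and a key
#'
#' Polynomial rolling hash of the key string combined with the master seed,
#' reduced modulo 2^31 - 1. All arithmetic stays below 2^53 so the result is
#' exact in doubles. Used to give every simulated recording its own
#' deterministic RNG stream.
#'
#' @param master_seed integer master seed of the study.
#' @param ... key components (coerced to character, joined with "/").
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(master_seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}

#' @noRd
stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "gipace_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' @noRd
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stopf("invalid_argument", "%s must be a positive integer, got %s", name,
          paste(x, collapse = ","))
  invisible(as.integer(x))
}

#' @noRd
zscore_cols <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  sg <- apply(m, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sg, "/")
}
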