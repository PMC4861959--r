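# Internal helpers shared across modules.

#' Derive a reproducible integer seed from a master seed and a string key
#'
#' Used to give every RBP its own deterministic random stream for
#' matched-control resampling: the stream depends only on the master seed
#' and the RBP identifier, never on iteration order.
#'
#' @param seed master integer seed.
#' @param key character scalar (e.g. an RBP id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, prime; keeps arithmetic exact in doubles
  h <- as.double(seed %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw n integers uniformly from an inclusive (min, max) range
#'
#' Safe for degenerate ranges: `sample(x:x, ...)` would fall through to
#' `sample.int(x)`, which is never what a range draw means.
#' @keywords internal
sample_range <- function(range, n) {
  if (range[1L] == range[2L]) return(rep(as.integer(range[1L]), n))
  sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Assert that a vector has no duplicated entries
#' @keywords internal
assert_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    stop(sprintf("duplicate %s: %s", what,
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
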