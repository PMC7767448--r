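#' Derive a stream seed from a base seed and identifiers
#'
#' Deterministic 31-bit hash used to key every source of randomness in the
#' pipeline to `(base_seed, stage, identifier)`, so that runs are reproducible
#' and independent stages draw from independent streams.
#'
#' @param base_seed Integer base seed.
#' @param ... Further identifiers (stage names, fold indices, sample ids);
#'   coerced to character.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
seed_for <- function(base_seed, ...) {
  ids <- unlist(lapply(list(...), as.character))
  h <- as.double(base_seed) %% 2147483647
  for (id in ids) {
    for (ch in utf8ToInt(id)) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# internal: stop with a classed condition, so callers can test error classes
stop_snnerp <- function(msg, class) {
  stop(structure(class = c(class, "snnerp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: check a scalar is a finite number
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
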