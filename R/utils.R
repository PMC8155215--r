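#' @importFrom rlang abort warn .data
#' @importFrom stats median pchisq qnorm rbeta rbinom rnbinom runif
NULL

# 31-bit polynomial rolling hash of a string; stable across sessions and
# platforms (utf8 code points, modulus 2^31 - 1).
string_hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic per-event seed derived from the master seed and the event id,
# so results do not depend on event order or on which other events are present.
event_seed <- function(master_seed, event_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 +
                string_hash31(event_id)) %% 2147483647)
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

check_counts <- function(inc, exc, call = rlang::caller_env()) {
  if (length(inc) != length(exc) && length(inc) != 1 && length(exc) != 1) {
    abort("`inc` and `exc` must have the same length (or length 1).",
          call = call)
  }
  bad <- !is_whole(inc) | !is_whole(exc) | inc < 0 | exc < 0
  if (any(bad)) {
    abort(
      sprintf(
        "junction counts must be non-negative integers (first offender at position %d: inc=%s, exc=%s)",
        which(bad)[1], format(inc[which(bad)[1]]), format(exc[which(bad)[1]])
      ),
      call = call
    )
  }
  invisible(TRUE)
}

# round-half-up at `digits` decimals; base round() is half-to-even, which
# would render e.g. 0.125 as 0.12 where reports require 0.13
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
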