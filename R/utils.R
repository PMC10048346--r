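# Internal helpers shared across modules.

# Derive a per-stage seed from one user-facing seed. Offsets keep stages
# decorrelated; result stays inside 32-bit integer range.
.deriveSeed <- function(seed, ...) {
  off <- sum(c(...) * (31L ^ seq_along(c(...))))
  as.integer((abs(as.numeric(seed)) * 1009 + off) %% 2147483629 + 1)
}

.assertFraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must be a single fraction %s", name,
                 if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && (if (positive) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}
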