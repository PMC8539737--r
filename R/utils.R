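# Internal helpers shared across modules.

# Run `expr` under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derived seeds must stay inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.double(seed) + as.double(offset)) %% 2147483587
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Squared Euclidean distances between rows of x (n x p) and rows of centers
# (k x p); returns an n x k matrix. Clamped at zero against FP cancellation.
rowdist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

`%s+%` <- function(a, b) paste0(a, b)
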