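# Internal utilities: activations, seeded sub-streams, numeric helpers.

.ngnn_env <- new.env(parent = emptyenv())

#' @importFrom rlang abort
ngnn_abort <- function(msg, class = "ngnn_error") {
  rlang::abort(msg, class = class)
}

# Named activations and their derivatives. The derivative is evaluated at the
# pre-activation value so caches only need to keep the linear output.
activation_fun <- function(name) {
  switch(name,
    leaky_relu = list(
      f  = function(z) z * (0.01 + 0.99 * (z > 0)),
      df = function(z) 0.01 + 0.99 * (z > 0)
    ),
    relu = list(
      f  = function(z) z * (z > 0),
      df = function(z) (z > 0) * 1
    ),
    tanh = list(
      f  = function(z) tanh(z),
      df = function(z) 1 - tanh(z)^2
    ),
    identity = list(
      f  = function(z) z,
      df = function(z) z * 0 + 1
    ),
    ngnn_abort(sprintf("unknown activation '%s'", name))
  )
}

# Independent deterministic sub-streams of one run seed (split / init / batch
# shuffling / noise draw each use their own stream). A fixed multiplicative
# congruential jump keeps every derived seed a valid 32-bit integer.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 48271 + 7919 * stream) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# max relative discrepancy, guarded near zero
rel_err <- function(a, b) {
  num <- abs(a - b)
  den <- pmax(abs(a) + abs(b), 1e-8)
  max(num / den)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    ngnn_abort(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
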