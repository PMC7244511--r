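# internal helpers shared across modules

# run `code` under a local RNG state seeded with `seed`; if seed is NULL the
# caller's RNG stream is used (and advanced) as-is
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) stopf("`%s` = %g is outside its allowed range", name, x)
  invisible(x)
}

# 20 standard amino acids, fixed order used throughout
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WINDOW_PAD <- "_"
WINDOW_WIDTH <- 15L
WINDOW_CENTER <- 8L
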