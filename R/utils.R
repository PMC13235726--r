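# Internal helpers: scoped RNG, sub-seed derivation, shared checks.

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable 31-bit hash of (seed, stage, id). Each stochastic stage of each
# pipeline draws from its own stream, so results do not depend on the order
# in which configurations are executed.
derive_seed <- function(seed, stage, id = "") {
  key <- paste(seed, stage, id, sep = "\r")
  codes <- utf8ToInt(key)
  h <- 2166136261 %% 2147483647
  for (cc in codes) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

stopf <- function(fmt, ..., class = NULL, data = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "scjudge_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

is_count_matrix <- function(x) inherits(x, "count_matrix")

# 30 visually distinct categorical colors (glasbey-style, hand-picked).
distinct_palette <- function() {
  c("#E6194B", "#3CB44B", "#4363D8", "#F58231", "#911EB4",
    "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE", "#008080",
    "#E6BEFF", "#9A6324", "#800000", "#AAFFC3", "#808000",
    "#FFD8B1", "#000075", "#808080", "#FFE119", "#000000",
    "#A9561E", "#5A0007", "#1CE6FF", "#6B7900", "#B903AA",
    "#D16100", "#7A4900", "#0000A6", "#63FFAC", "#004D43")
}
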