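`%||%` <- function(x, y) if (is.null(x)) y else x

abort_depscreen <- function(msg, class) {
  stop(structure(
    class = c(class, "depscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Deterministic 32-bit substream key: order-independent per-unit seeds derived
# from a master seed and a unit index (kept below 2^31 - 1 for set.seed()).
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
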