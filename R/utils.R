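# Small internal helpers shared across modules.

# stop with a clean message, no call
stop_bbb <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, finite = TRUE, positive = FALSE) {
  if (!is.numeric(x)) stop_bbb("`", name, "` must be numeric")
  if (finite && any(!is.finite(x))) stop_bbb("`", name, "` must be finite")
  if (positive && any(x <= 0)) stop_bbb("`", name, "` must be positive")
  invisible(x)
}

# resolve a data-frame column by name, with a helpful error
pull_col <- function(data, col, what = "column") {
  if (!col %in% names(data)) {
    stop_bbb("missing ", what, " `", col, "` in input data")
  }
  data[[col]]
}

# derive a child seed from a user seed, staying inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 11 * k) %% 2147483647L)
}

# numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
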