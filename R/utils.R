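# Internal assertion helpers. Error messages name the offending values so
# contract violations are diagnosable from the message alone.

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that_ <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_f(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

# (H, W, C, N) internal batch <-> per-channel matrix with (HW*N) rows
cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

uncmat <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

# extract sample n of an (H, W, C, N) batch as an (H, W, C) array
batch_sample <- function(x, n) {
  d <- dim(x)
  array(x[, , , n], d[1:3])
}

# public channels-first (C, H, W) array -> internal (H, W, C, 1) batch
chw_to_batch <- function(x) {
  d <- dim(x)
  array(aperm(x, c(2L, 3L, 1L)), c(d[2L], d[3L], d[1L], 1L))
}

# internal (H, W, C, N) batch, sample 1 -> public (C, H, W)
batch_to_chw <- function(x) {
  aperm(batch_sample(x, 1L), c(3L, 1L, 2L))
}
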