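# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed for an independent random stream
#'
#' One root seed drives several independent noise streams (sensor noise,
#' onset jitter, artifacts, ...) so that toggling one component does not shift
#' the draws of another. Child seeds are a deterministic function of the root
#' seed and a stream label.
#'
#' @param seed integer root seed (or `NULL` for no seeding).
#' @param stream character stream label.
#' @return an integer-valued seed below 2^31, or `NULL` if `seed` is `NULL`.
#' @export
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + h * 104729) %% 2147483629)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# peak-to-peak amplitude of a vector
p2p <- function(x) {
  r <- range(x)
  r[2L] - r[1L]
}

stop_ckc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

# row-wise Euclidean norms of a numeric matrix
row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}
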