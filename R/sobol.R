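#' Sobol low-discrepancy sequence
#'
#' Generates points of the Sobol sequence in \code{[0, 1)^dim} using the
#' gray-code construction with the standard Joe--Kuo direction numbers
#' (dimensions up to 64). An optional digital shift -- a per-dimension
#' bitwise XOR with a random integer -- decouples independent runs while
#' preserving the low-discrepancy structure in base 2.
#'
#' The first point of the unshifted sequence (the origin) is skipped by
#' default, the usual convention when the points parameterise draws.
#'
#' @param n number of points.
#' @param dim dimension, between 1 and 64.
#' @param shift optional integer vector of length \code{dim} of digital
#'   shifts in \code{[0, 2^30)}; \code{NULL} for the raw sequence.
#' @param skip_origin drop the all-zero first point (default \code{TRUE};
#'   ignored when a shift is supplied, as the origin is then shifted too).
#' @return an \code{n x dim} matrix of points in \code{[0, 1)}.
#' @examples
#' head(sobol_points(8, 2))
#' @export
sobol_points <- function(n, dim, shift = NULL, skip_origin = TRUE) {
  stopifnot(n >= 1, dim >= 1)
  if (dim > length(.sobol_poly)) {
    stop("sobol_points() supports at most ", length(.sobol_poly), " dimensions")
  }
  if (!is.null(shift)) {
    stopifnot(length(shift) == dim)
    shift <- as.integer(shift)
    skip_origin <- FALSE
  }
  nbits <- 30L
  n_gen <- if (skip_origin) n + 1L else n
  v <- .sobol_directions(dim, nbits)      # list of integer vectors [nbits]
  x <- integer(dim)
  out <- matrix(0L, n_gen, dim)
  for (k in seq_len(n_gen - 1L)) {
    # index of the lowest zero bit of (k - 1)
    c <- 1L
    kk <- k - 1L
    while (bitwAnd(kk, 1L) == 1L) {
      kk <- bitwShiftR(kk, 1L)
      c <- c + 1L
    }
    for (j in seq_len(dim)) x[j] <- bitwXor(x[j], v[[j]][c])
    out[k + 1L, ] <- x
  }
  if (skip_origin) out <- out[-1L, , drop = FALSE]
  if (!is.null(shift)) {
    for (j in seq_len(dim)) out[, j] <- bitwXor(out[, j], shift[j])
  }
  out / 2^nbits
}

# Direction numbers v_c (c = 1..nbits) for each dimension, scaled to nbits bits.
.sobol_directions <- function(dim, nbits) {
  lapply(seq_len(dim), function(j) {
    v <- integer(nbits)
    if (j == 1L) {
      # first dimension: van der Corput sequence in base 2
      for (i in seq_len(nbits)) v[i] <- bitwShiftL(1L, nbits - i)
      return(v)
    }
    p <- .sobol_poly[j]
    m <- .sobol_minit[[j]]
    s <- length(m)
    # inner polynomial coefficients a_1..a_{s-1} (leading/constant bits dropped)
    a <- integer(max(s - 1L, 0L))
    for (k in seq_len(s - 1L)) {
      a[k] <- bitwAnd(bitwShiftR(p, s - k), 1L)
    }
    for (i in seq_len(min(s, nbits))) v[i] <- bitwShiftL(m[i], nbits - i)
    if (nbits > s) {
      for (i in (s + 1L):nbits) {
        vi <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
        for (k in seq_len(s - 1L)) {
          if (a[k] == 1L) vi <- bitwXor(vi, v[i - k])
        }
        v[i] <- vi
      }
    }
    v
  })
}
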