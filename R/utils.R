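#' Wrap phase values into (-pi, pi]
#'
#' @param x Numeric vector, matrix or array of phase values in radians.
#' @return Object of the same shape with every value wrapped into the
#'   principal interval \code{(-pi, pi]}.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * ceiling((x - pi) / (2 * pi))
  # rounding can land exactly on the open end of the interval
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# circular shift so that element 1 (DC for FFT output) lands at
# floor(n/2)+1, matching the usual fftshift convention
shift_index <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1

fftshift2 <- function(m) {
  m[shift_index(nrow(m), nrow(m) %/% 2), shift_index(ncol(m), ncol(m) %/% 2),
    drop = FALSE]
}

ifftshift2 <- function(m) {
  m[shift_index(nrow(m), nrow(m) - nrow(m) %/% 2),
    shift_index(ncol(m), ncol(m) - ncol(m) %/% 2), drop = FALSE]
}

dc_bin <- function(dim) dim %/% 2 + 1

# Physical pixel-centre coordinate grids in micrometres.  Pixel (1,1) is
# the top-left corner; centres sit at (index - 0.5) * pixel_pitch.
pixel_grids <- function(config) {
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  x <- (seq_len(nc) - 0.5) * config$pixel_pitch
  y <- (seq_len(nr) - 0.5) * config$pixel_pitch
  list(
    x = matrix(x, nr, nc, byrow = TRUE),
    y = matrix(y, nr, nc, byrow = FALSE)
  )
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_holo <- function(msg, class) {
  stop(structure(class = c(class, "holoRI_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
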