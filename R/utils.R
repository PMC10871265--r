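#' @useDynLib projclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp rnorm runif sd var cor dist median setNames
#' @importFrom utils head read.delim write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions
#' do not perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# sub-seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

pc_log <- function(...) {
  if (isTRUE(getOption("projclust.verbose", FALSE))) message(...)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' @param phi,theta,psi angles in radians (intrinsic Z-Y-Z convention).
#' @return 3x3 rotation matrix.
#' @keywords internal
euler_zyz <- function(phi, theta, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0,
                             -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a),
                             0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

# bilinear resize of a matrix to nr x nc, sampling at pixel centers
resize_bilinear <- function(img, nr, nc) {
  h <- nrow(img); w <- ncol(img)
  if (h == nr && w == nc) return(img)
  # map output pixel centers into input coordinates (1-based, edge aligned)
  ys <- if (nr == 1) (h + 1) / 2 else seq(1, h, length.out = nr)
  xs <- if (nc == 1) (w + 1) / 2 else seq(1, w, length.out = nc)
  y0 <- pmin(pmax(floor(ys), 1), h - 1); y1 <- y0 + 1
  x0 <- pmin(pmax(floor(xs), 1), w - 1); x1 <- x0 + 1
  wy <- ys - y0; wx <- xs - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(wy, nr, nc); wxm <- matrix(wx, nr, nc, byrow = TRUE)
  (1 - wy) * ((1 - wxm) * a + wxm * b) + wy * ((1 - wxm) * c_ + wxm * d)
}

# pad a matrix with zeros to size nr x nc, content centered
pad_center <- function(img, nr, nc) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(nr >= h, nc >= w)
  out <- matrix(0, nr, nc)
  r0 <- floor((nr - h) / 2); c0 <- floor((nc - w) / 2)
  out[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- img
  out
}
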