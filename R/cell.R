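#' Unit cell
#'
#' Construct a unit cell from lattice lengths (in angstrom) and angles
#' (in degrees). The reciprocal metric tensor is precomputed and cached;
#' it must be positive definite, which rules out degenerate cells.
#'
#' @param a,b,c Lattice lengths in angstrom, all `> 0`.
#' @param alpha,beta,gamma Lattice angles in degrees, all in `(0, 180)`.
#'
#' @return An object of class `"unit_cell"`: a list with the six cell
#'   parameters plus `metric` (direct metric tensor G) and `reciprocal_metric`
#'   (G* = G^-1).
#' @examples
#' unit_cell(18.2872, 18.6661, 6.6222)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!(a > 0 && b > 0 && c > 0))
    stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev))
    stop("degenerate cell: metric tensor is not positive definite")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 metric = G, reciprocal_metric = solve(G)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Reciprocal-space resolution d* of a reflection
#'
#' Computes d* = sqrt(h' G* h) in inverse angstrom, with G* the reciprocal
#' metric tensor of the cell. d* is zero only for the (0,0,0) index.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer Miller indices: a length-3 vector or an n-by-3 matrix.
#'
#' @return Numeric vector of d* values (1/angstrom), one per index triple.
#' @examples
#' d_star(unit_cell(10, 10, 10), c(1, 0, 0))  # 0.1
#' @export
d_star <- function(cell, hkl) {
  if (!inherits(cell, "unit_cell")) stop("'cell' must be a unit_cell")
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  if (ncol(h) != 3L) stop("'hkl' must have three columns")
  Gs <- cell$reciprocal_metric
  sqrt(pmax(rowSums((h %*% Gs) * h), 0))
}
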