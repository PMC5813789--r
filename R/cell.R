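#' Construct a unit cell
#'
#' A unit cell is described by its six parameters: the three edge lengths
#' \code{a}, \code{b}, \code{c} (in Angstrom) and the three inter-edge angles
#' \code{alpha} (between b and c), \code{beta} (between c and a) and
#' \code{gamma} (between a and b), in degrees.  The constructor validates that
#' the parameters describe a genuine (positive-definite) lattice: all lengths
#' positive, all angles strictly between 0 and 180 degrees, and a real,
#' positive cell volume.
#'
#' @param a,b,c Cell edge lengths in Angstrom, > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class \code{"unit_cell"}: a named numeric vector of
#'   the six parameters with the cell volume (Angstrom^3) attached as the
#'   \code{"volume"} attribute.
#' @examples
#' uc <- unit_cell(77.3, 91.8, 114.6)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p)))
    stop("unit cell parameters must be finite numbers")
  if (any(p[1:3] <= 0))
    stop("cell edges a, b, c must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  # squared scalar triple product term; must be > 0 for a positive-definite
  # metric tensor
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0)
    stop("cell angles do not define a positive-definite lattice ",
         "(imaginary cell volume)")
  structure(p, volume = a * b * c * sqrt(v2), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g  (V=%.6g A^3)\n",
              x[["a"]], x[["b"]], x[["c"]],
              x[["alpha"]], x[["beta"]], x[["gamma"]],
              attr(x, "volume")))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  if (is.numeric(x) && length(x) == 6)
    return(unit_cell(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]]))
  stop("cannot interpret input as a unit cell")
}

#' Cell volume
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  attr(as_unit_cell(cell), "volume")
}

#' Real-space basis matrix of a unit cell
#'
#' Builds an orthonormal-frame basis with the crystallographic convention:
#' \code{a} along x, \code{b} in the xy plane.  Columns are the real-space
#' basis vectors.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return A 3 x 3 matrix whose columns are the a, b, c vectors (Angstrom).
#' @export
cell_basis <- function(cell) {
  cell <- as_unit_cell(cell)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  sg <- sin(cell[["gamma"]] * pi / 180)
  cx <- cc * cb
  cy <- cc * (ca - cb * cg) / sg
  cz2 <- cc^2 - cx^2 - cy^2
  cz <- sqrt(max(cz2, 0))
  matrix(c(a, 0, 0,
           b * cg, b * sg, 0,
           cx, cy, cz), nrow = 3,
         dimnames = list(c("x", "y", "z"), c("a", "b", "c")))
}

# metric tensor G (real space) and its inverse (reciprocal metric)
cell_metric <- function(cell) {
  B <- cell_basis(cell)
  crossprod(B)
}

reciprocal_metric <- function(cell) {
  solve(cell_metric(cell))
}

#' Face diagonals of a unit cell
#'
#' Each principal face of the cell is a parallelogram spanned by two edge
#' vectors u, v and has two diagonals, |u + v| and |u - v|.  For right angles
#' the two coincide.  The convention used by default is the |u + v| diagonal
#' (cosine term added); the \code{convention} flag switches to |u - v|.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param convention \code{"sum"} for |u + v| (default) or \code{"difference"}
#'   for |u - v|.
#' @return A named numeric vector \code{c(d_ab, d_bc, d_ca)} of the three face
#'   diagonals in Angstrom.
#' @examples
#' face_diagonals(unit_cell(10, 20, 30))
#' @export
face_diagonals <- function(cell, convention = c("sum", "difference")) {
  cell <- as_unit_cell(cell)
  convention <- match.arg(convention)
  sgn <- if (convention == "sum") 1 else -1
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  c(d_ab = sqrt(a^2 + b^2 + sgn * 2 * a * b * cg),
    d_bc = sqrt(b^2 + cc^2 + sgn * 2 * b * cc * ca),
    d_ca = sqrt(cc^2 + a^2 + sgn * 2 * cc * a * cb))
}

new_alcv_result <- function(deltas, argmax_pair = NULL) {
  structure(list(delta_a = deltas[[1]], delta_b = deltas[[2]],
                 delta_c = deltas[[3]],
                 alcv = max(deltas), argmax_pair = argmax_pair),
            class = "alcv_result")
}

#' @export
print.alcv_result <- function(x, ...) {
  cat(sprintf("aLCV = %.4g A  (delta_a=%.4g, delta_b=%.4g, delta_c=%.4g)\n",
              x$alcv, x$delta_a, x$delta_b, x$delta_c))
  if (!is.null(x$argmax_pair))
    cat("  realized by pair:", paste(x$argmax_pair, collapse = " / "), "\n")
  invisible(x)
}

#' Absolute linear cell variation (aLCV) between two unit cells
#'
#' The aLCV measures unit-cell isomorphism of two crystals in Angstrom.  For
#' each of the three principal faces the corresponding face diagonals of the
#' two cells are compared; the three absolute differences are the quantities
#' delta_a (ab face), delta_b (bc face) and delta_c (ca face), and
#' \deqn{aLCV = \max(\Delta a, \Delta b, \Delta c).}
#' Because a diagonal depends simultaneously on the two spanning edges and
#' the angle between them, the aLCV captures combined length and angle
#' variation in a single physically interpretable number.
#'
#' @param cell1,cell2 \code{\link{unit_cell}} objects.
#' @param convention Face-diagonal convention, see
#'   \code{\link{face_diagonals}}.
#' @return An \code{"alcv_result"}: list with \code{delta_a}, \code{delta_b},
#'   \code{delta_c}, \code{alcv} (all Angstrom) and \code{argmax_pair}.
#' @examples
#' pair_alcv(unit_cell(10, 20, 30), unit_cell(11, 20, 30))
#' @export
pair_alcv <- function(cell1, cell2, convention = c("sum", "difference")) {
  convention <- match.arg(convention)
  d1 <- face_diagonals(cell1, convention)
  d2 <- face_diagonals(cell2, convention)
  new_alcv_result(abs(d1 - d2))
}

# n x 3 matrix of face diagonals for a list of cells
.diagonal_matrix <- function(cells, convention = "sum") {
  t(vapply(cells, function(cl) face_diagonals(cl, convention), numeric(3)))
}

#' Pairwise aLCV matrix for a group of cells
#'
#' @param cells List of \code{\link{unit_cell}} objects (optionally named).
#' @param convention Face-diagonal convention.
#' @return Symmetric matrix of pairwise aLCV values in Angstrom.
#' @export
alcv_matrix <- function(cells, convention = c("sum", "difference")) {
  convention <- match.arg(convention)
  D <- .diagonal_matrix(cells, convention)
  n <- nrow(D)
  M <- matrix(0, n, n)
  for (f in 1:3) {
    M <- pmax(M, abs(outer(D[, f], D[, f], "-")))
  }
  ids <- names(cells)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(M) <- list(ids, ids)
  M
}

#' aLCV of a group of unit cells
#'
#' For more than two cells the pairwise aLCV is evaluated over all unordered
#' pairs and the group value is the maximum obtained; \code{argmax_pair}
#' identifies one pair realizing it.
#'
#' @inheritParams alcv_matrix
#' @return An \code{"alcv_result"} as in \code{\link{pair_alcv}}, with
#'   \code{argmax_pair} set to the identifiers of a maximizing pair.
#' @export
group_alcv <- function(cells, convention = c("sum", "difference")) {
  convention <- match.arg(convention)
  if (length(cells) < 2)
    stop("group_alcv needs at least 2 cells")
  M <- alcv_matrix(cells, convention)
  idx <- which(M == max(M), arr.ind = TRUE)
  # deterministic pick: smallest row, then column
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  ids <- rownames(M)
  pair <- c(ids[idx[[1]]], ids[idx[[2]]])
  d1 <- face_diagonals(cells[[idx[[1]]]], convention)
  d2 <- face_diagonals(cells[[idx[[2]]]], convention)
  new_alcv_result(abs(d1 - d2), argmax_pair = pair)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes d = 1 / |h a* + k b* + l c*| from the reciprocal basis of the
#' cell.  Vectorized over reflection indices.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param h,k,l Integer Miller indices (equal-length vectors); (0,0,0) is
#'   rejected.
#' @return d-spacings in Angstrom.
#' @examples
#' resolution_of(unit_cell(10, 10, 10), 1, 0, 0)  # 10 A
#' @export
resolution_of <- function(cell, h, k, l) {
  if (any(h == 0 & k == 0 & l == 0))
    stop("resolution undefined for (0,0,0)")
  Gs <- reciprocal_metric(cell)
  H <- cbind(h, k, l)
  inv_d2 <- rowSums((H %*% Gs) * H)
  1 / sqrt(inv_d2)
}
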