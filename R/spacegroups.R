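# Space-group support: hard-coded operator tables for the common
# macromolecular groups handled by this package, reciprocal-space ASU
# mapping, systematic absences and possible-reflection counting.
#
# Operators are stored as (R, t): x' = R x + t with R an integer 3x3 matrix
# acting on fractional coordinates and t a fractional translation.
# Reciprocal indices transform as row vectors: h' = h R.

.op <- function(r, t = c(0, 0, 0)) {
  list(R = matrix(as.integer(r), 3, 3, byrow = TRUE), t = t)
}

# free cell parameters by crystal system (descriptor columns for clustering)
.SYSTEM_FREE <- list(
  triclinic    = c("a", "b", "c", "alpha", "beta", "gamma"),
  monoclinic   = c("a", "b", "c", "beta"),
  orthorhombic = c("a", "b", "c"),
  tetragonal   = c("a", "c"),
  trigonal     = c("a", "c"),
  hexagonal    = c("a", "c"),
  cubic        = "a"
)

.SPACEGROUPS <- list(
  P1 = list(symbol = "P1", system = "triclinic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1))
  )),
  P21 = list(symbol = "P21", system = "monoclinic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 1/2, 0))
  )),
  C2 = list(symbol = "C2", system = "monoclinic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1)),
    .op(c(1,0,0, 0,1,0, 0,0,1), c(1/2, 1/2, 0)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1), c(1/2, 1/2, 0))
  )),
  P222 = list(symbol = "P222", system = "orthorhombic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(-1,0,0, 0,-1,0, 0,0,1)),
    .op(c(1,0,0, 0,-1,0, 0,0,-1)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1))
  )),
  P2221 = list(symbol = "P2221", system = "orthorhombic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(-1,0,0, 0,-1,0, 0,0,1), c(0, 0, 1/2)),
    .op(c(1,0,0, 0,-1,0, 0,0,-1)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 0, 1/2))
  )),
  P212121 = list(symbol = "P212121", system = "orthorhombic", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(-1,0,0, 0,-1,0, 0,0,1), c(1/2, 0, 1/2)),
    .op(c(1,0,0, 0,-1,0, 0,0,-1), c(1/2, 1/2, 0)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 1/2, 1/2))
  )),
  P4 = list(symbol = "P4", system = "tetragonal", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(0,-1,0, 1,0,0, 0,0,1)),
    .op(c(-1,0,0, 0,-1,0, 0,0,1)),
    .op(c(0,1,0, -1,0,0, 0,0,1))
  )),
  P43212 = list(symbol = "P43212", system = "tetragonal", ops = list(
    .op(c(1,0,0, 0,1,0, 0,0,1)),
    .op(c(0,-1,0, 1,0,0, 0,0,1), c(1/2, 1/2, 3/4)),
    .op(c(-1,0,0, 0,-1,0, 0,0,1), c(0, 0, 1/2)),
    .op(c(0,1,0, -1,0,0, 0,0,1), c(1/2, 1/2, 1/4)),
    .op(c(1,0,0, 0,-1,0, 0,0,-1), c(1/2, 1/2, 1/4)),
    .op(c(0,-1,0, -1,0,0, 0,0,-1), c(0, 0, 1/2)),
    .op(c(-1,0,0, 0,1,0, 0,0,-1), c(1/2, 1/2, 3/4)),
    .op(c(0,1,0, 1,0,0, 0,0,-1))
  ))
)

.normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[ _()]", "", symbol))
  # subscripted variants like "P2(1)2(1)2(1)" already collapse above
  s
}

#' Space-group information
#'
#' Looks up one of the supported space groups and returns its symbol, crystal
#' system, symmetry operators and the number of free cell parameters of its
#' crystal system (6 triclinic, 4 monoclinic, 3 orthorhombic, 2 tetragonal /
#' trigonal / hexagonal, 1 cubic).
#'
#' Supported groups: P1, P21, C2, P222, P2221, P212121, P4, P43212.  Symbols
#' are matched case-insensitively and ignoring spaces.  Extension is a matter
#' of appending an operator table to the internal registry.
#'
#' @param symbol Hermann-Mauguin symbol, e.g. \code{"P2221"} or
#'   \code{"P 21 21 21"}.
#' @return An object of class \code{"spacegroup_info"}: list with
#'   \code{symbol}, \code{system}, \code{ops} (list of \code{R} matrix +
#'   \code{t} translation), \code{n_free}.
#' @export
spacegroup_info <- function(symbol) {
  if (inherits(symbol, "spacegroup_info")) return(symbol)
  key <- .normalize_sg_symbol(symbol)
  sg <- .SPACEGROUPS[[key]]
  if (is.null(sg))
    stop("unsupported space group '", symbol, "'; supported: ",
         paste(names(.SPACEGROUPS), collapse = ", "))
  sg$n_free <- length(.SYSTEM_FREE[[sg$system]])
  class(sg) <- "spacegroup_info"
  sg
}

#' @export
print.spacegroup_info <- function(x, ...) {
  cat(sprintf("space group %s (%s, %d operators, %d free cell parameters)\n",
              x$symbol, x$system, length(x$ops), x$n_free))
  invisible(x)
}

#' Free cell parameters of a crystal system
#'
#' @param system Crystal system name (triclinic, monoclinic, orthorhombic,
#'   tetragonal, trigonal, hexagonal, cubic).
#' @return Character vector of the independent cell parameters.
#' @export
free_cell_parameters <- function(system) {
  out <- .SYSTEM_FREE[[match.arg(system, names(.SYSTEM_FREE))]]
  out
}

# check that the operator set is closed under composition (mod lattice
# translations); used by the test suite to validate the hard-coded tables
.sg_is_closed <- function(sg) {
  sg <- spacegroup_info(sg)
  key <- function(op) paste(c(op$R, round(op$t %% 1, 9)), collapse = ",")
  have <- vapply(sg$ops, key, character(1))
  for (o1 in sg$ops) for (o2 in sg$ops) {
    comp <- list(R = o1$R %*% o2$R, t = (o1$R %*% o2$t + o1$t)[, 1] %% 1)
    if (!key(comp) %in% have) return(FALSE)
  }
  TRUE
}

# unique rotation parts (point group), as a list of 3x3 integer matrices
.point_rotations <- function(sg) {
  sg <- spacegroup_info(sg)
  rots <- lapply(sg$ops, `[[`, "R")
  keys <- vapply(rots, function(R) paste(R, collapse = ","), character(1))
  rots[!duplicated(keys)]
}

# lexicographic key for (h,k,l) triples; base must exceed the index range
.hkl_key <- function(h, k, l, base) {
  (h * base + k) * base + l
}

#' Map reflections to the asymmetric unit
#'
#' Reduces Miller indices to a canonical representative of their orbit under
#' the point-group rotations of the space group plus Friedel inversion.  The
#' representative is the lexicographically greatest (h, k, l) tuple of the
#' orbit, which makes the mapping deterministic, idempotent and
#' orbit-invariant without reference to any published ASU convention.
#'
#' @param h,k,l Integer index vectors of equal length.
#' @param space_group A symbol or \code{\link{spacegroup_info}}.
#' @return A data.frame with columns \code{h}, \code{k}, \code{l} of the
#'   representatives.
#' @examples
#' map_to_asu(c(1, -1), c(2, -2), c(3, -3), "P1")  # both rows -> (1,2,3)
#' @export
map_to_asu <- function(h, k, l, space_group) {
  sg <- spacegroup_info(space_group)
  rots <- .point_rotations(sg)
  n <- length(h)
  stopifnot(length(k) == n, length(l) == n)
  if (n == 0) return(data.frame(h = integer(), k = integer(), l = integer()))
  base <- 2 * max(abs(c(h, k, l)), 1) + 3
  best_key <- rep(-Inf, n)
  best <- matrix(0L, n, 3)
  H <- cbind(h, k, l)
  for (R in rots) {
    img <- H %*% R
    for (sgn in c(1L, -1L)) {        # Friedel inversion
      im <- img * sgn
      keyv <- .hkl_key(im[, 1], im[, 2], im[, 3], base)
      upd <- keyv > best_key
      if (any(upd)) {
        best[upd, ] <- im[upd, , drop = FALSE]
        best_key[upd] <- keyv[upd]
      }
    }
  }
  data.frame(h = as.integer(best[, 1]), k = as.integer(best[, 2]),
             l = as.integer(best[, 3]))
}

# vector of TRUE where reflection is systematically absent:
# exists op (R,t) with h R == h and fractional h.t != 0
.systematic_absent <- function(h, k, l, sg) {
  sg <- spacegroup_info(sg)
  H <- cbind(h, k, l)
  absent <- rep(FALSE, length(h))
  for (op in sg$ops) {
    img <- H %*% op$R
    fixed <- img[, 1] == H[, 1] & img[, 2] == H[, 2] & img[, 3] == H[, 3]
    if (!any(fixed)) next
    phase <- (H[, 1] * op$t[1] + H[, 2] * op$t[2] + H[, 3] * op$t[3]) %% 1
    absent <- absent | (fixed & abs(phase) > 1e-9 & abs(phase - 1) > 1e-9)
  }
  absent
}

#' Enumerate possible unique reflections to a resolution limit
#'
#' Lists all distinct ASU representatives with d-spacing >= \code{d_min},
#' excluding (0,0,0) and the systematic absences of the group.  The index
#' search box is bounded by |h| <= a/d_min (and similarly for k, l), which is
#' rigorous because h equals the projection of the scattering vector onto the
#' real-space cell edge.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param space_group Symbol or \code{\link{spacegroup_info}}.
#' @param d_min High-resolution limit in Angstrom, > 0.
#' @return Data.frame of unique reflections: \code{h}, \code{k}, \code{l},
#'   \code{d} (Angstrom), sorted by decreasing d.
#' @export
possible_reflections <- function(cell, space_group, d_min) {
  if (!is.numeric(d_min) || d_min <= 0) stop("d_min must be > 0")
  cell <- as_unit_cell(cell)
  sg <- spacegroup_info(space_group)
  hmax <- floor(cell[["a"]] / d_min)
  kmax <- floor(cell[["b"]] / d_min)
  lmax <- floor(cell[["c"]] / d_min)
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- resolution_of(cell, grid$h, grid$k, grid$l)
  keep <- d >= d_min - 1e-9
  grid <- grid[keep, ]; d <- d[keep]
  ok <- !.systematic_absent(grid$h, grid$k, grid$l, sg)
  grid <- grid[ok, ]; d <- d[ok]
  asu <- map_to_asu(grid$h, grid$k, grid$l, sg)
  base <- 2 * max(abs(unlist(asu)), 1) + 3
  keyv <- .hkl_key(asu$h, asu$k, asu$l, base)
  first <- !duplicated(keyv)
  out <- data.frame(h = asu$h[first], k = asu$k[first], l = asu$l[first],
                    d = d[first])
  out[order(-out$d, -out$h, -out$k, -out$l), , drop = FALSE]
}

#' Count possible unique reflections to a resolution limit
#'
#' @inheritParams possible_reflections
#' @return Integer count of distinct, non-absent ASU representatives with
#'   d >= d_min.
#' @export
count_possible_reflections <- function(cell, space_group, d_min) {
  nrow(possible_reflections(cell, space_group, d_min))
}

# does the cell satisfy the angular/length constraints of the system?
.cell_matches_system <- function(cell, system, tol = 1e-6) {
  cell <- as_unit_cell(cell)
  ang_ok <- function(x, v) abs(cell[[x]] - v) < tol
  switch(system,
    triclinic = TRUE,
    monoclinic = ang_ok("alpha", 90) && ang_ok("gamma", 90),
    orthorhombic = ang_ok("alpha", 90) && ang_ok("beta", 90) &&
      ang_ok("gamma", 90),
    tetragonal = ang_ok("alpha", 90) && ang_ok("beta", 90) &&
      ang_ok("gamma", 90) && abs(cell[["a"]] - cell[["b"]]) < tol,
    trigonal = ,
    hexagonal = ang_ok("alpha", 90) && ang_ok("beta", 90) &&
      ang_ok("gamma", 120) && abs(cell[["a"]] - cell[["b"]]) < tol,
    cubic = ang_ok("alpha", 90) && ang_ok("beta", 90) &&
      ang_ok("gamma", 90) && abs(cell[["a"]] - cell[["b"]]) < tol &&
      abs(cell[["b"]] - cell[["c"]]) < tol,
    stop("unknown crystal system '", system, "'"))
}
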