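# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check.

# face diagonals via explicit 3-D vector construction of the cell
diagonals_vector_oracle <- function(cell, convention = "sum") {
  B <- cell_basis(cell)
  sgn <- if (convention == "sum") 1 else -1
  c(d_ab = sqrt(sum((B[, "a"] + sgn * B[, "b"])^2)),
    d_bc = sqrt(sum((B[, "b"] + sgn * B[, "c"])^2)),
    d_ca = sqrt(sum((B[, "c"] + sgn * B[, "a"])^2)))
}

# d-spacing via explicit reciprocal-basis construction
resolution_vector_oracle <- function(cell, h, k, l) {
  B <- cell_basis(cell)
  Bstar <- t(solve(B))   # columns a*, b*, c*
  s <- Bstar %*% rbind(h, k, l)
  1 / sqrt(colSums(s^2))
}

# brute-force symmetry orbit of one index triple (rotations + Friedel)
orbit_bruteforce <- function(h, k, l, sg) {
  sg <- spacegroup_info(sg)
  rots <- unique(lapply(sg$ops, `[[`, "R"))
  out <- list()
  for (R in rots) {
    im <- as.integer(c(h, k, l) %*% R)
    out <- c(out, list(im, -im))
  }
  unique(out)
}

# random valid cell with moderate obliquity
random_cell <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 20, 80), runif(1, 20, 80),
                        runif(1, 20, 80), runif(1, 70, 110),
                        runif(1, 70, 110), runif(1, 70, 110)),
              silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}

# hand-built dataset: explicit observation table, P1 triclinic-free cell
tiny_dataset <- function(h, k, l, intensity, sigma = 1,
                         batch = 1, cell = unit_cell(20, 25, 30),
                         sg = "P1", label = "tiny", id = NA) {
  n <- length(h)
  new_dataset(data.frame(h = h, k = k, l = l,
                         batch = rep_len(batch, n),
                         intensity = intensity,
                         sigma = rep_len(sigma, n)),
              cell = cell, space_group = sg, label = label, id = id)
}

# small, fast campaign defaults for merge/filter/prune tests
small_config <- function(seed, ...) {
  defaults <- list(seed = seed, cell = c(30, 35, 40, 90, 90, 90),
                   space_group = "P2221", n_groups = 1,
                   datasets_per_group = 4, n_batches = 10, coverage = 0.3,
                   jitter_length = 0.05, jitter_angle = 0, d_min = 6)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# grossly perturb one dataset's intensities (non-isomorphous content)
spoil_dataset <- function(ds, seed = 1, factor = 4) {
  set.seed(seed)
  ob <- ds$observations
  ob$intensity <- ob$intensity *
    exp(stats::rnorm(nrow(ob), 0, log(factor)))
  new_dataset(ob, ds$cell, ds$space_group, label = ds$label,
              crystal = ds$crystal, id = ds$id, path = ds$path)
}
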