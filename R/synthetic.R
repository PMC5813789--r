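# Synthetic multi-crystal campaign simulator.  Emulates the statistical
# structure the merging method assumes: isomorphism groups with small cell
# jitter, partial rotation sweeps, per-dataset scale/B heterogeneity,
# optional per-image radiation damage and Gaussian measurement noise -- with
# full ground truth, so every downstream module is testable without real
# diffraction data.

#' Simulation configuration
#'
#' Builds and validates the configuration of a synthetic multi-crystal
#' campaign.  Defaults describe a modest macromolecular campaign: a
#' protein-complex-sized orthorhombic cell in P2221 merged at 4 Angstrom,
#' two isomorphism groups of six partial sweeps each, 0.2 Angstrom
#' within-group cell jitter, per-dataset scales in [0.5, 2] and B factors in
#' [0, 10] Angstrom^2, and noise sigma^2 = sigma0^2 + alpha I giving roughly
#' 5 percent relative error at the mean intensity.  Radiation damage is off
#' by default.
#'
#' @param seed Mandatory RNG seed; fixes the full campaign output.
#' @param cell Reference unit cell (six numbers or \code{\link{unit_cell}}).
#' @param space_group Space-group symbol.
#' @param n_groups Number of isomorphism groups G.
#' @param datasets_per_group Datasets in each group.
#' @param group_offset Inter-group cell offset in Angstrom (applied
#'   cumulatively to the a and c edges per group index).
#' @param jitter_length,jitter_angle Within-group Gaussian jitter sd on free
#'   cell lengths (Angstrom) and free angles (degrees).
#' @param n_batches Images per sweep.
#' @param coverage Fraction of the unique (ASU) reflection list sampled per
#'   batch, in (0, 1].
#' @param sweep \code{"random"} (each batch samples a random ASU subset) or
#'   \code{"wedge"} (contiguous, deterministic index blocks emulating
#'   rotation wedges; dataset-dependent phase).
#' @param scale_range,b_range Per-dataset uniform ranges for the true scale
#'   k and isotropic B (Angstrom^2).
#' @param beta B-factor growth per batch (Angstrom^2/image) on damaged
#'   datasets.
#' @param delta Fractional intensity drift per batch applied to a seeded
#'   random half of the reflections of damaged datasets (systematic
#'   late-batch bias).
#' @param damage_datasets Integer indices of the datasets that suffer
#'   radiation damage (empty = none).
#' @param sigma0,alpha Noise model: sigma^2 = sigma0^2 + alpha * |I|.
#' @param mean_intensity Mean of the exponential (acentric Wilson) true
#'   intensity distribution.
#' @param d_min High-resolution limit of the simulated reflection list
#'   (Angstrom).
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed,
                       cell = c(77.3, 91.8, 114.6, 90, 90, 90),
                       space_group = "P2221",
                       n_groups = 2,
                       datasets_per_group = 6,
                       group_offset = 2,
                       jitter_length = 0.2,
                       jitter_angle = 0.1,
                       n_batches = 20,
                       coverage = 0.08,
                       sweep = c("random", "wedge"),
                       scale_range = c(0.5, 2),
                       b_range = c(0, 10),
                       beta = 0,
                       delta = 0,
                       damage_datasets = integer(0),
                       sigma0 = 1,
                       alpha = 0.25,
                       mean_intensity = 100,
                       d_min = 4) {
  if (missing(seed) || !is.numeric(seed))
    stop("sim_config requires a numeric seed")
  sweep <- match.arg(sweep)
  cfg <- list(seed = as.integer(seed), cell = as_unit_cell(cell),
              space_group = spacegroup_info(space_group)$symbol,
              n_groups = as.integer(n_groups),
              datasets_per_group = as.integer(datasets_per_group),
              group_offset = group_offset,
              jitter_length = jitter_length, jitter_angle = jitter_angle,
              n_batches = as.integer(n_batches), coverage = coverage,
              sweep = sweep, scale_range = scale_range, b_range = b_range,
              beta = beta, delta = delta,
              damage_datasets = as.integer(damage_datasets),
              sigma0 = sigma0, alpha = alpha,
              mean_intensity = mean_intensity, d_min = d_min)
  if (cfg$n_groups < 1 || cfg$datasets_per_group < 1)
    stop("need at least one group and one dataset per group")
  if (cfg$coverage <= 0 || cfg$coverage > 1)
    stop("coverage must be in (0, 1]")
  if (cfg$jitter_length < 0 || cfg$jitter_angle < 0 || cfg$sigma0 < 0 ||
      cfg$alpha < 0 || cfg$beta < 0)
    stop("jitter, noise and damage parameters must be >= 0")
  if (cfg$d_min <= 0) stop("d_min must be > 0")
  if (cfg$n_batches < 1) stop("need at least one batch per sweep")
  structure(cfg, class = "sim_config")
}

# jittered cell around a centre, respecting the crystal system's constraints
.jitter_cell <- function(centre, system, sd_len, sd_ang) {
  p <- unclass(as_unit_cell(centre))[1:6]
  free <- free_cell_parameters(system)
  for (f in intersect(free, c("a", "b", "c")))
    p[[f]] <- p[[f]] + stats::rnorm(1, 0, sd_len)
  for (f in intersect(free, c("alpha", "beta", "gamma")))
    p[[f]] <- p[[f]] + stats::rnorm(1, 0, sd_ang)
  if (system %in% c("tetragonal", "trigonal", "hexagonal"))
    p[["b"]] <- p[["a"]]
  if (system == "cubic") p[["b"]] <- p[["c"]] <- p[["a"]]
  do.call(unit_cell, as.list(p))
}

.simulate_impl <- function(config, outlier_ids = integer(0),
                           outlier_offset = 0) {
  cfg <- config
  set.seed(cfg$seed)
  sg <- spacegroup_info(cfg$space_group)
  n_total <- cfg$n_groups * cfg$datasets_per_group
  if (length(outlier_ids) && max(outlier_ids) > n_total)
    stop("outlier ids exceed the number of datasets")
  # ground-truth reflection list and intensities on the reference cell
  refl <- possible_reflections(cfg$cell, sg, cfg$d_min)
  nref <- nrow(refl)
  I_true <- stats::rexp(nref, rate = 1 / cfg$mean_intensity)
  damaged_set <- sort(sample.int(nref, size = floor(nref / 2)))
  is_damaged_refl <- logical(nref); is_damaged_refl[damaged_set] <- TRUE
  # per-dataset truths
  group_of <- rep(seq_len(cfg$n_groups), each = cfg$datasets_per_group)
  k_true <- stats::runif(n_total, cfg$scale_range[1], cfg$scale_range[2])
  B_true <- stats::runif(n_total, cfg$b_range[1], cfg$b_range[2])
  m_per_batch <- max(1L, round(cfg$coverage * nref))
  datasets <- vector("list", n_total)
  cells <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- group_of[[i]]
    centre <- unclass(cfg$cell)[1:6]
    centre[c("a", "c")] <- centre[c("a", "c")] + (g - 1) * cfg$group_offset
    cl <- .jitter_cell(centre, sg$system, cfg$jitter_length,
                       cfg$jitter_angle)
    oi <- match(i, outlier_ids)
    if (!is.na(oi)) {
      # mutually distinct large offsets: different axis and magnitude per
      # outlier, so outliers are non-isomorphous with everything including
      # each other
      p <- unclass(cl)[1:6]
      axis <- c("a", "b", "c")[((oi - 1) %% 3) + 1]
      p[[axis]] <- p[[axis]] + outlier_offset * (1 + 0.5 * (oi - 1))
      if (sg$system %in% c("tetragonal", "trigonal", "hexagonal"))
        p[["b"]] <- p[["a"]]
      cl <- do.call(unit_cell, as.list(p))
    }
    cells[[i]] <- cl
    damaged <- i %in% cfg$damage_datasets
    beta_i <- if (damaged) cfg$beta else 0
    delta_i <- if (damaged) cfg$delta else 0
    rows <- vector("list", cfg$n_batches)
    for (b in seq_len(cfg$n_batches)) {
      pick <- if (cfg$sweep == "random") {
        sample.int(nref, m_per_batch)
      } else {
        ((i * 7 + (b - 1) * m_per_batch) + seq_len(m_per_batch) - 1) %%
          nref + 1
      }
      d <- resolution_of(cl, refl$h[pick], refl$k[pick], refl$l[pick])
      s2 <- 1 / (4 * d^2)
      geff <- k_true[[i]] * exp(-2 * (B_true[[i]] + beta_i * b) * s2)
      I_eff <- I_true[pick] *
        (1 + delta_i * b * is_damaged_refl[pick])
      sig <- sqrt(cfg$sigma0^2 + cfg$alpha * abs(geff * I_eff))
      I_obs <- geff * I_eff + stats::rnorm(m_per_batch, 0, sig)
      # a noise-free configuration still needs positive reported sigmas
      rows[[b]] <- data.frame(h = refl$h[pick], k = refl$k[pick],
                              l = refl$l[pick], batch = b,
                              intensity = I_obs, sigma = pmax(sig, 1e-8))
    }
    datasets[[i]] <- new_dataset(do.call(rbind, rows), cell = cl,
                                 space_group = sg$symbol,
                                 label = sprintf("sim_g%d_d%02d", g, i),
                                 crystal = sprintf("xtal%02d",
                                                   ceiling(i / 2)),
                                 id = i)
  }
  conditions <- data.frame(
    dataset_id = vapply(datasets, `[[`, character(1), "label"),
    crystal_id = vapply(datasets, `[[`, character(1), "crystal"),
    BC = "bc1", CC = "cry1", DH = "dh1", CO = "no",
    HA = paste0("ha", group_of))
  truth <- list(
    reflections = cbind(refl, intensity = I_true,
                        damaged = is_damaged_refl),
    k = k_true, B = B_true, group = group_of,
    outliers = outlier_ids,
    damage = list(datasets = cfg$damage_datasets, beta = cfg$beta,
                  delta = cfg$delta))
  list(datasets = datasets, conditions = conditions, truth = truth,
       config = cfg)
}

#' Simulate a multi-crystal data-collection campaign
#'
#' Generates \code{n_groups * datasets_per_group} synthetic sweeps.  Each
#' dataset's cell is its group centre plus Gaussian jitter; each batch
#' samples the configured fraction of the unique reflection list; observed
#' intensities are \eqn{k\,e^{-2(B+\beta\,batch)s^2}(1+drift)\,I_{true} +
#' noise} with the noise sigma reported alongside.  Fully deterministic for
#' a fixed seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{datasets} (list of \code{\link{new_dataset}}),
#'   \code{conditions} (per-dataset metadata data.frame whose HA code equals
#'   the isomorphism group), \code{truth} (ground-truth reflection
#'   intensities, per-dataset (k, B), group memberships, damage settings)
#'   and the \code{config}.
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .simulate_impl(config)
}

#' Simulate a campaign with planted non-isomorphous outliers
#'
#' As \code{\link{simulate_campaign}}, but the datasets listed last receive
#' mutually distinct cell offsets of magnitude >= \code{offset} Angstrom
#' (different axes and increasing magnitudes), making them strongly
#' non-isomorphous with all other datasets and with each other.  The truth
#' records their ids.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_outliers Number of planted outliers (< total datasets).
#' @param offset Minimum cell offset in Angstrom; must exceed the
#'   within-group jitter or the design is unidentifiable (error).
#' @return As \code{\link{simulate_campaign}}; \code{truth$outliers} holds
#'   the planted dataset indices.
#' @export
planted_outlier_campaign <- function(config, n_outliers, offset) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_groups * config$datasets_per_group
  if (n_outliers < 0 || n_outliers >= n_total)
    stop("n_outliers must be in [0, total datasets)")
  if (n_outliers > 0 && offset <= config$jitter_length)
    stop("outlier offset must exceed the within-group jitter ",
         "(unidentifiable design)")
  ids <- if (n_outliers > 0)
    seq(n_total - n_outliers + 1, n_total) else integer(0)
  .simulate_impl(config, outlier_ids = ids, outlier_offset = offset)
}

#' Write a simulated campaign to disk
#'
#' Emits one UXT file per dataset, a \code{filelist.txt} naming them in
#' order, the conditions TSV and the ground truth as JSON.
#'
#' @param campaign A \code{\link{simulate_campaign}} result.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(campaign$datasets))
  for (i in seq_along(campaign$datasets)) {
    ds <- campaign$datasets[[i]]
    paths[[i]] <- file.path(dir, paste0(ds$label, ".uxt"))
    write_unmerged(ds, paths[[i]])
  }
  writeLines(paths, file.path(dir, "filelist.txt"))
  utils::write.table(campaign$conditions, file.path(dir, "conditions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- campaign$truth
  jsonlite::write_json(
    list(reflections = tr$reflections, k = tr$k, B = tr$B,
         group = tr$group, outliers = tr$outliers, damage = tr$damage),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation configuration from a key=value file
#'
#' Flat text format: one \code{key=value} per line, \code{#} comments;
#' vector values comma-separated (e.g. \code{cell=77.3,91.8,114.6,90,90,90}).
#' Keys mirror the arguments of \code{\link{sim_config}}; \code{seed} is
#' mandatory.
#'
#' @param path Config file path.
#' @return A \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad))
    stop(path, ": malformed config line: ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  args <- list()
  char_keys <- c("space_group", "sweep")
  for (i in seq_along(keys)) {
    v <- strsplit(vals[[i]], ",", fixed = TRUE)[[1]]
    args[[keys[[i]]]] <- if (keys[[i]] %in% char_keys) trimws(v)
                         else as.numeric(v)
  }
  do.call(sim_config, args)
}
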