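# Joint scaling of multiple datasets, merging to unique reflections, and the
# merging-statistics block (Rmerge, Rmeas, Rpim, completeness, multiplicity,
# CC1/2- and Mn(I/sd)-based resolution estimates).
#
# The scaling model is per-dataset: g_j(s) = k_j * exp(-2 * B_j * s^2) with
# s = 1/(2d); one dataset is the gauge reference with (k, B) = (1, 0).

.dataset_key <- function(ds, j) {
  if (!is.na(ds$id)) as.character(ds$id) else ds$label
}

# flatten datasets into one observation table with ASU keys; applies the
# resolution cutoff (d >= resolution_max) and sorts deterministically by
# (unique reflection, dataset, batch)
.assemble_obs <- function(datasets, resolution_max = NULL) {
  stopifnot(length(datasets) >= 1)
  sgs <- unique(vapply(datasets, `[[`, character(1), "space_group"))
  if (length(sgs) > 1)
    warning("datasets declare different space groups (",
            paste(sgs, collapse = ", "), "); using ", sgs[[1]])
  sg <- spacegroup_info(sgs[[1]])
  parts <- vector("list", length(datasets))
  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]
    ob <- ds$observations
    d <- resolution_of(ds$cell, ob$h, ob$k, ob$l)
    keep <- if (is.null(resolution_max)) rep(TRUE, length(d))
            else d >= resolution_max
    ob <- ob[keep, , drop = FALSE]; d <- d[keep]
    if (nrow(ob) == 0) { parts[[j]] <- NULL; next }
    asu <- map_to_asu(ob$h, ob$k, ob$l, sg)
    parts[[j]] <- data.frame(j = j, h = asu$h, k = asu$k, l = asu$l,
                             batch = ob$batch, d = d, s2 = 1 / (4 * d^2),
                             intensity = ob$intensity, sigma = ob$sigma)
  }
  obs <- do.call(rbind, parts)
  if (is.null(obs) || nrow(obs) == 0)
    stop("no observations survive the resolution cutoff")
  base <- 2 * max(abs(c(obs$h, obs$k, obs$l)), 1) + 3
  obs$key <- .hkl_key(obs$h, obs$k, obs$l, base)
  obs <- obs[order(obs$key, obs$j, obs$batch), , drop = FALSE]
  rownames(obs) <- NULL
  # mean cell over datasets, used for completeness denominators and shells
  cellmat <- vapply(datasets, function(ds) unclass(ds$cell)[1:6], numeric(6))
  mean_cell <- do.call(unit_cell, as.list(rowMeans(cellmat)))
  structure(obs, space_group = sg$symbol, mean_cell = mean_cell,
            ids = vapply(seq_along(datasets),
                         function(j) .dataset_key(datasets[[j]], j),
                         character(1)),
            resolution_max = resolution_max)
}

.model_g <- function(model, j, s2) {
  model$k[j] * exp(-2 * model$B[j] * s2)
}

.identity_model <- function(ids, resolution_max = NULL) {
  structure(list(ids = ids, k = rep(1, length(ids)),
                 B = rep(0, length(ids)), reference = 1,
                 iterations = 0L, residual = NA_real_, converged = TRUE,
                 resolution_max = resolution_max),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("scaling model: %d datasets (reference '%s'), %d iterations%s\n",
              length(x$ids), x$ids[[x$reference]], x$iterations,
              if (x$converged) ", converged" else " (NOT converged)"))
  print(data.frame(id = x$ids, k = x$k, B = x$B))
  invisible(x)
}

#' Fit per-dataset scale factors and isotropic B factors
#'
#' Minimizes the weighted least-squares objective
#' \deqn{\sum_h \sum_j \sum_i w_{hij}\,(I_{hij} - g_j(s_h)\langle I_h\rangle)^2}
#' with \eqn{g_j(s) = k_j e^{-2 B_j s^2}}, \eqn{s = 1/(2d)} and weights
#' \eqn{w = 1/\sigma^2}, by alternating (a) the closed-form update of the
#' merged means \eqn{\langle I_h\rangle} and (b) a per-dataset weighted
#' log-linear regression of \eqn{\log(I/\langle I\rangle)} on \eqn{s^2} for
#' \eqn{(k_j, B_j)}.  The reference dataset fixes the gauge at exactly
#' \eqn{(k, B) = (1, 0)}.  Iteration stops when the relative change of the
#' residual drops below \code{tol} or after \code{max_iter} iterations;
#' the procedure is deterministic.
#'
#' @param datasets List of \code{\link{new_dataset}} objects sharing a space
#'   group.  A dataset sharing fewer than 10 unique reflections with the rest
#'   triggers a warning; one sharing none is an error (disjoint data cannot
#'   be scaled together).
#' @param resolution_max Optional high-resolution cutoff in Angstrom
#'   (observations with d < cutoff are ignored).
#' @param reference Index of the gauge dataset (default 1).
#' @param tol Relative residual-change convergence threshold (default 1e-8).
#' @param max_iter Maximum iterations (default 200).
#' @return An object of class \code{"scaling_model"}: \code{ids}, \code{k},
#'   \code{B} (per dataset, aligned with the input list), \code{reference},
#'   \code{iterations}, final \code{residual}, \code{converged}.
#' @export
fit_scales <- function(datasets, resolution_max = NULL, reference = 1,
                       tol = 1e-8, max_iter = 200) {
  obs <- .assemble_obs(datasets, resolution_max)
  ids <- attr(obs, "ids")
  nds <- length(datasets)
  if (nds == 1) return(.identity_model(ids, resolution_max))
  # overlap diagnostics
  keyj <- unique(obs[c("key", "j")])
  shared_keys <- keyj$key[duplicated(keyj$key) |
                          duplicated(keyj$key, fromLast = TRUE)]
  shared_per_ds <- vapply(seq_len(nds), function(j)
    length(unique(keyj$key[keyj$j == j & keyj$key %in% shared_keys])),
    integer(1))
  if (any(shared_per_ds == 0))
    stop("dataset(s) ", paste(ids[shared_per_ds == 0], collapse = ", "),
         " share no unique reflections with the rest; cannot scale ",
         "disjoint data")
  if (any(shared_per_ds < 10))
    warning("dataset(s) ",
            paste(ids[shared_per_ds < 10], collapse = ", "),
            " share fewer than 10 unique reflections with the rest; ",
            "scale estimates may be unstable")
  k <- rep(1, nds); B <- rep(0, nds)
  w <- 1 / obs$sigma^2
  fkey <- factor(obs$key)
  res_prev <- Inf
  res_trace <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    g <- k[obs$j] * exp(-2 * B[obs$j] * obs$s2)
    num <- rowsum(w * g * obs$intensity, fkey)
    den <- rowsum(w * g^2, fkey)
    Ibar <- (num / pmax(den, 1e-300))[fkey]
    res <- sum(w * (obs$intensity - g * Ibar)^2)
    res_trace <- c(res_trace, res)
    # per-dataset log-linear regression on positive ratio pairs; the
    # candidate (k, B) is accepted only if it lowers that dataset's part of
    # the objective (given the current merged means), so the alternating
    # scheme is a guaranteed descent
    ok <- obs$intensity > 0 & Ibar > 0
    y <- log(obs$intensity[ok] / Ibar[ok])
    x <- obs$s2[ok]
    wt <- w[ok] * (g[ok] * Ibar[ok])^2
    jj <- obs$j[ok]
    for (j in seq_len(nds)) {
      sel <- jj == j
      if (sum(sel) < 2) next
      sw <- wt[sel]; sx <- x[sel]; sy <- y[sel]
      xm <- sum(sw * sx) / sum(sw)
      ym <- sum(sw * sy) / sum(sw)
      sxx <- sum(sw * (sx - xm)^2)
      b <- if (sxx > 1e-12) sum(sw * (sx - xm) * (sy - ym)) / sxx else 0
      a <- ym - b * xm
      k_c <- exp(a); B_c <- -b / 2
      oj <- obs$j == j
      part <- function(kk, bb) {
        gg <- kk * exp(-2 * bb * obs$s2[oj])
        sum(w[oj] * (obs$intensity[oj] - gg * Ibar[oj])^2)
      }
      # exact closed-form k given the candidate B sharpens the step
      e <- exp(-2 * B_c * obs$s2[oj])
      den_k <- sum(w[oj] * (e * Ibar[oj])^2)
      if (den_k > 1e-300) {
        k_r <- sum(w[oj] * obs$intensity[oj] * e * Ibar[oj]) / den_k
        if (k_r > 0 && part(k_r, B_c) < part(k_c, B_c)) k_c <- k_r
      }
      if (part(k_c, B_c) <= part(k[j], B[j])) {
        k[j] <- k_c
        B[j] <- B_c
      }
    }
    # gauge fix on the reference dataset
    B <- B - B[reference]
    k <- k / k[reference]
    if (res < 1e-20 ||
        (is.finite(res_prev) &&
         abs(res_prev - res) <= tol * max(res_prev, 1e-300))) {
      converged <- TRUE
      res_prev <- res
      break
    }
    res_prev <- res
  }
  structure(list(ids = ids, k = k, B = B, reference = reference,
                 iterations = iters, residual = res_prev,
                 residual_trace = res_trace,
                 converged = converged, resolution_max = resolution_max),
            class = "scaling_model")
}

#' Merge scaled datasets to unique reflections
#'
#' Observations are corrected by the inverse of their dataset's scale
#' function, mapped to the asymmetric unit, cut at the resolution limit and
#' combined per unique reflection by inverse-variance weighted mean (plain
#' mean available via \code{weighting}); the merged sigma is the standard
#' error of the weighted mean.
#'
#' @param datasets List of \code{\link{new_dataset}} objects.
#' @param model A \code{\link{fit_scales}} model, or \code{NULL} for the
#'   identity model.
#' @param resolution_max Optional high-resolution cutoff in Angstrom.
#' @param weighting \code{"invvar"} (default) or \code{"plain"}.
#' @return A data.frame of class \code{"merged_set"} with columns \code{h},
#'   \code{k}, \code{l}, \code{d}, \code{intensity}, \code{sigma},
#'   \code{nobs}; attributes record the space group, mean cell, resolution
#'   range, applied cutoff and contributing dataset ids.
#' @export
merge_datasets <- function(datasets, model = NULL, resolution_max = NULL,
                           weighting = c("invvar", "plain")) {
  weighting <- match.arg(weighting)
  obs <- .assemble_obs(datasets, resolution_max)
  if (is.null(model)) model <- .identity_model(attr(obs, "ids"),
                                               resolution_max)
  g <- .model_g(model, obs$j, obs$s2)
  Ic <- obs$intensity / g
  sc <- obs$sigma / g
  w <- if (weighting == "invvar") 1 / sc^2 else rep(1, length(sc))
  fkey <- factor(obs$key)
  sw <- rowsum(w, fkey)
  Im <- rowsum(w * Ic, fkey) / sw
  # standard error of the weighted mean
  sig <- if (weighting == "invvar") sqrt(1 / sw)
         else sqrt(rowsum(w * sc^2, fkey)) / sw
  nobs <- rowsum(rep(1L, nrow(obs)), fkey)
  first <- !duplicated(obs$key)
  out <- data.frame(h = obs$h[first], k = obs$k[first], l = obs$l[first],
                    d = obs$d[first],
                    intensity = as.numeric(Im),
                    sigma = as.numeric(sig),
                    nobs = as.integer(nobs))
  out <- out[order(-out$d, -out$h, -out$k, -out$l), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, space_group = attr(obs, "space_group"),
            mean_cell = attr(obs, "mean_cell"),
            resolution_range = range(out$d),
            resolution_max = resolution_max,
            contributing = attr(obs, "ids"),
            weighting = weighting,
            class = c("merged_set", "data.frame"))
}

#' Write a merged reflection set as TSV
#'
#' @param merged A \code{\link{merge_datasets}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_merged <- function(merged, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#MERGED", "h\tk\tl\tI\tsigI\tnobs",
               paste(merged$h, merged$k, merged$l,
                     .num_fmt(merged$intensity), .num_fmt(merged$sigma),
                     merged$nobs, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Equal reciprocal-volume resolution shells
#'
#' Computes shell boundaries equally spaced in 1/d^3 between the observed
#' low-resolution limit and the high-resolution cutoff of a merged set.
#'
#' @param merged A \code{\link{merge_datasets}} result (or numeric vector of
#'   d-spacings).
#' @param n_shells Number of shells, >= 2.
#' @return Numeric vector of n_shells + 1 boundaries in Angstrom, strictly
#'   decreasing.
#' @export
shell_binning <- function(merged, n_shells) {
  if (!is.numeric(n_shells) || n_shells < 2)
    stop("n_shells must be >= 2")
  d <- if (is.data.frame(merged)) merged$d else merged
  lo <- max(d)
  hi <- if (is.data.frame(merged) && !is.null(attr(merged, "resolution_max")))
    attr(merged, "resolution_max") else min(d)
  .recip_shell_bounds(lo, hi, n_shells)
}

# R-factor sums over multiply-measured uniques; x = corrected intensities,
# fkey restricted
.rstats <- function(Ic, fkey, Ibar_obs, nh_obs) {
  sel <- nh_obs >= 2
  if (!any(sel)) return(list(rmerge = NA_real_, rmeas = NA_real_,
                             rpim = NA_real_))
  Ic <- Ic[sel]; f <- droplevels(fkey[sel]); Ib <- Ibar_obs[sel]
  nh <- nh_obs[sel]
  dev <- abs(Ic - Ib)
  denom <- sum(Ic)
  if (abs(denom) < 1e-300) return(list(rmerge = NA_real_, rmeas = NA_real_,
                                       rpim = NA_real_))
  list(rmerge = sum(dev) / denom,
       rmeas = sum(sqrt(nh / (nh - 1)) * dev) / denom,
       rpim = sum(sqrt(1 / (nh - 1)) * dev) / denom)
}

# deterministic alternating half-set means per unique; obs assumed sorted by
# (key, dataset, batch).  Returns data.frame(key, m1, m2) for uniques with
# n >= 2.
.half_set_means <- function(Ic, key) {
  n <- length(Ic)
  runlen <- rle(key)$lengths
  pos <- sequence(runlen)
  fkey <- factor(key, levels = unique(key))
  odd <- pos %% 2 == 1
  n1 <- rowsum(as.numeric(odd), fkey)
  n2 <- rowsum(as.numeric(!odd), fkey)
  s1 <- rowsum(Ic * odd, fkey)
  s2 <- rowsum(Ic * (!odd), fkey)
  ok <- n1 > 0 & n2 > 0
  data.frame(key = unique(key)[ok], m1 = (s1 / pmax(n1, 1))[ok],
             m2 = (s2 / pmax(n2, 1))[ok])
}

# linear interpolation of the d where a per-shell statistic crosses a
# threshold, walking shells from low to high resolution; clamped to d_cut
.crossing_resolution <- function(d_mid, stat, threshold, d_cut) {
  ok <- !is.na(stat)
  d_mid <- d_mid[ok]; stat <- stat[ok]
  if (length(stat) == 0) return(NA_real_)
  if (stat[1] < threshold) return(max(d_mid[1], d_cut))
  cross <- which(stat < threshold)[1]
  if (is.na(cross)) return(d_cut)
  i0 <- cross - 1
  frac <- (stat[i0] - threshold) / (stat[i0] - stat[cross])
  res <- d_mid[i0] + frac * (d_mid[cross] - d_mid[i0])
  max(res, d_cut)
}

#' Merging statistics for a scaled, merged dataset
#'
#' Computes the canonical agreement and coverage statistics of a merged
#' multi-crystal dataset, overall and in equal reciprocal-volume resolution
#' shells:
#' \itemize{
#' \item \eqn{R_{merge} = \sum_h\sum_i |I_i - \langle I_h\rangle| /
#'   \sum_h\sum_i I_i} over uniques measured at least twice;
#' \item \eqn{R_{meas}} and \eqn{R_{pim}}: the same sums with per-unique
#'   factors \eqn{\sqrt{n_h/(n_h-1)}} and \eqn{\sqrt{1/(n_h-1)}};
#' \item completeness (percent of theoretically possible unique reflections
#'   observed, to the applied cutoff) and multiplicity (observations per
#'   unique);
#' \item CC1/2: Pearson correlation of deterministic alternating half-set
#'   means; Mn(I/sd): mean merged I over merged sigma;
#' \item resolution estimates where per-shell CC1/2 crosses 0.3 and where
#'   per-shell Mn(I/sd) crosses 2, linearly interpolated between shell
#'   midpoints and clamped to the applied cutoff.
#' }
#' When no unique reflection is measured twice the R statistics and CC1/2
#' are reported as \code{NA} (undefined), not numbers.
#'
#' @param datasets List of \code{\link{new_dataset}} objects.
#' @param model Optional \code{\link{fit_scales}} model (identity if NULL).
#' @param merged Optional precomputed \code{\link{merge_datasets}} result
#'   (recomputed if NULL).
#' @param resolution_max Optional high-resolution cutoff in Angstrom.
#' @param n_shells Number of resolution shells (default 10).
#' @param weighting Merging weight scheme, as in \code{\link{merge_datasets}}.
#' @return An object of class \code{"merge_stats"}: list with
#'   \code{overall} (named list: rmerge, rmeas, rpim, completeness,
#'   multiplicity, mn_i_sd, cc_half, resolution_cc, resolution_isd,
#'   resolution_max, n_unique, n_obs) and \code{shells} (per-shell
#'   data.frame of the same statistics).
#' @export
compute_stats <- function(datasets, model = NULL, merged = NULL,
                          resolution_max = NULL, n_shells = 10,
                          weighting = c("invvar", "plain")) {
  weighting <- match.arg(weighting)
  obs <- .assemble_obs(datasets, resolution_max)
  ids <- attr(obs, "ids")
  if (is.null(model)) model <- .identity_model(ids, resolution_max)
  if (is.null(merged))
    merged <- merge_datasets(datasets, model, resolution_max, weighting)
  sg <- attr(obs, "space_group")
  cell <- attr(obs, "mean_cell")
  g <- .model_g(model, obs$j, obs$s2)
  Ic <- obs$intensity / g
  fkey <- factor(obs$key, levels = unique(obs$key))
  nh <- as.integer(table(fkey))
  # align merged means with the observation order
  mkey_base <- 2 * max(abs(c(merged$h, merged$k, merged$l)), 1) + 3
  base <- 2 * max(abs(c(obs$h, obs$k, obs$l)), 1) + 3
  mkey <- .hkl_key(merged$h, merged$k, merged$l, base)
  midx <- match(unique(obs$key), mkey)
  Ibar_u <- merged$intensity[midx]
  nh_obs <- nh[as.integer(fkey)]
  Ibar_obs <- Ibar_u[as.integer(fkey)]
  d_cut <- if (is.null(resolution_max)) min(merged$d) else resolution_max
  # overall statistics
  rs <- .rstats(Ic, fkey, Ibar_obs, nh_obs)
  possible <- possible_reflections(cell, sg, d_cut)
  # completeness counts observed uniques inside the theoretical set only
  # (borderline d-spacings of individual cells can fall outside it)
  pbase <- 2 * max(abs(c(merged$h, merged$k, merged$l,
                         possible$h, possible$k, possible$l)), 1) + 3
  pkey <- .hkl_key(possible$h, possible$k, possible$l, pbase)
  in_possible <- .hkl_key(merged$h, merged$k, merged$l, pbase) %in% pkey
  completeness <- 100 * sum(in_possible) / max(nrow(possible), 1)
  multiplicity <- nrow(obs) / nrow(merged)
  mn_i_sd <- mean(merged$intensity / merged$sigma)
  hs <- .half_set_means(Ic, obs$key)
  cc_half <- if (nrow(hs) >= 3 && stats::sd(hs$m1) > 0 &&
                 stats::sd(hs$m2) > 0)
    stats::cor(hs$m1, hs$m2) else NA_real_
  # per-shell table
  bounds <- .recip_shell_bounds(max(merged$d), d_cut, n_shells)
  s3 <- (1 / bounds^3)
  d_mid <- ((s3[-length(s3)] + s3[-1]) / 2)^(-1 / 3)
  sh_u <- .shell_index(merged$d, bounds)       # per unique
  sh_o <- .shell_index(obs$d, bounds)          # per observation
  sh_p <- .shell_index(possible$d, bounds)     # per possible unique
  sh_hs <- .shell_index(merged$d[midx][match(hs$key, unique(obs$key))],
                        bounds)
  shells <- lapply(seq_len(n_shells), function(s) {
    iu <- sh_u == s; io <- sh_o == s
    n_u <- sum(iu); n_o <- sum(io)
    n_p <- sum(sh_p == s)
    n_in <- sum(iu & in_possible)
    if (n_u == 0)
      return(data.frame(shell = s, d_hi = bounds[s + 1], d_lo = bounds[s],
                        d_mid = d_mid[s], n_unique = 0L, n_obs = 0L,
                        rmerge = NA_real_, rmeas = NA_real_,
                        rpim = NA_real_, completeness = 0,
                        multiplicity = NA_real_, mn_i_sd = NA_real_,
                        cc_half = NA_real_))
    rss <- .rstats(Ic[io], droplevels(fkey[io]), Ibar_obs[io], nh_obs[io])
    ih <- sh_hs == s
    cc <- if (sum(ih) >= 3 && stats::sd(hs$m1[ih]) > 0 &&
              stats::sd(hs$m2[ih]) > 0)
      stats::cor(hs$m1[ih], hs$m2[ih]) else NA_real_
    data.frame(shell = s, d_hi = bounds[s + 1], d_lo = bounds[s],
               d_mid = d_mid[s], n_unique = n_u, n_obs = n_o,
               rmerge = rss$rmerge, rmeas = rss$rmeas, rpim = rss$rpim,
               completeness = 100 * n_in / max(n_p, 1),
               multiplicity = n_o / n_u,
               mn_i_sd = mean(merged$intensity[iu] / merged$sigma[iu]),
               cc_half = cc)
  })
  shells <- do.call(rbind, shells)
  resolution_cc <- .crossing_resolution(shells$d_mid, shells$cc_half, 0.3,
                                        d_cut)
  resolution_isd <- .crossing_resolution(shells$d_mid, shells$mn_i_sd, 2,
                                         d_cut)
  structure(list(
    overall = list(rmerge = rs$rmerge, rmeas = rs$rmeas, rpim = rs$rpim,
                   completeness = completeness,
                   multiplicity = multiplicity,
                   mn_i_sd = mn_i_sd, cc_half = cc_half,
                   resolution_cc = resolution_cc,
                   resolution_isd = resolution_isd,
                   resolution_max = d_cut,
                   n_unique = nrow(merged), n_obs = nrow(obs)),
    shells = shells,
    contributing = ids),
    class = "merge_stats")
}

#' @export
print.merge_stats <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0(
    "merged %d observations into %d uniques (%d datasets)\n",
    "  Rmerge %.4g  Rmeas %.4g  Rpim %.4g\n",
    "  completeness %.1f%%  multiplicity %.2f  Mn(I/sd) %.2f  CC1/2 %.4g\n",
    "  resolution: CC1/2=0.3 at %.2f A, Mn(I/sd)=2 at %.2f A (cutoff %.2f A)\n"),
    o$n_obs, o$n_unique, length(x$contributing),
    o$rmerge, o$rmeas, o$rpim, o$completeness, o$multiplicity,
    o$mn_i_sd, o$cc_half, o$resolution_cc, o$resolution_isd,
    o$resolution_max))
  invisible(x)
}

#' One-row summary of merging statistics
#'
#' @param stats A \code{\link{compute_stats}} result.
#' @return Data.frame with the columns conventionally tabulated for merged
#'   datasets: Rmeas, Rpim, completeness (percent), multiplicity, the two
#'   resolution estimates and the applied cutoff.
#' @export
stats_row <- function(stats) {
  o <- stats$overall
  data.frame(rmeas = o$rmeas, rpim = o$rpim,
             completeness = o$completeness,
             multiplicity = o$multiplicity,
             resolution_cc = o$resolution_cc,
             resolution_isd = o$resolution_isd,
             resolution_max = o$resolution_max)
}

#' Write merging statistics to JSON
#'
#' @param stats A \code{\link{compute_stats}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_merge_stats <- function(stats, path) {
  jsonlite::write_json(list(overall = stats$overall,
                            shells = stats$shells,
                            contributing = stats$contributing),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
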