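# Dataset model and unmerged-reflection file I/O ("UXT" dialect: a plain
# TSV exchange format for unmerged intensities, one sweep per file).

#' Construct a dataset (one crystal sweep)
#'
#' A dataset bundles the unmerged observations of one rotation sweep with its
#' unit cell and space group.  Observations carry Miller indices, the image
#' (batch) number within the sweep, an intensity on an arbitrary linear scale
#' and its standard uncertainty.
#'
#' @param observations Data.frame with integer columns \code{h}, \code{k},
#'   \code{l}, \code{batch} (>= 1) and numeric \code{intensity},
#'   \code{sigma} (> 0).
#' @param cell A \code{\link{unit_cell}}.
#' @param space_group Symbol or \code{\link{spacegroup_info}}; the cell must
#'   satisfy the metric constraints of the group's crystal system.
#' @param label Human-readable dataset label.
#' @param crystal Crystal identifier (several sweeps may share one crystal).
#' @param id Serial number within a run (assigned by
#'   \code{\link{analysis_mode}}; may be \code{NA} for standalone datasets).
#' @param path Source file path, if any.
#' @return An object of class \code{"xdataset"}.
#' @export
new_dataset <- function(observations, cell, space_group, label = "dataset",
                        crystal = NA_character_, id = NA_integer_,
                        path = NA_character_) {
  cell <- as_unit_cell(cell)
  sg <- spacegroup_info(space_group)
  obs <- as.data.frame(observations)
  need <- c("h", "k", "l", "batch", "intensity", "sigma")
  if (!all(need %in% names(obs)))
    stop("observations must have columns: ", paste(need, collapse = ", "))
  obs <- obs[need]
  if (nrow(obs) == 0) stop("dataset must contain at least one observation")
  for (cn in c("h", "k", "l", "batch")) {
    if (any(obs[[cn]] != round(obs[[cn]])))
      stop("column '", cn, "' must be integer-valued")
    obs[[cn]] <- as.integer(obs[[cn]])
  }
  if (any(obs$batch < 1)) stop("batch numbers must be >= 1")
  if (any(!is.finite(obs$sigma)) || any(obs$sigma <= 0))
    stop("sigma must be positive and finite")
  if (!.cell_matches_system(cell, sg$system))
    stop("cell is inconsistent with the ", sg$system,
         " constraints of space group ", sg$symbol)
  structure(list(id = as.integer(id), label = label, crystal = crystal,
                 cell = cell, space_group = sg$symbol,
                 observations = obs,
                 batch_range = range(obs$batch), path = path),
            class = "xdataset")
}

#' @export
print.xdataset <- function(x, ...) {
  cat(sprintf("dataset '%s' (id %s, crystal %s): %d observations, batches %d-%d, %s\n",
              x$label, ifelse(is.na(x$id), "?", x$id),
              ifelse(is.na(x$crystal), "?", x$crystal),
              nrow(x$observations), x$batch_range[1], x$batch_range[2],
              x$space_group))
  print(x$cell)
  invisible(x)
}

.num_fmt <- function(x) sprintf("%.17g", x)

#' Write a dataset to an unmerged-exchange TSV (UXT) file
#'
#' The UXT dialect is a UTF-8, LF-terminated TSV: header lines
#' \code{#CELL a b c alpha beta gamma}, \code{#SPACEGROUP symbol},
#' \code{#DATASET label}, \code{#CRYSTAL id}, followed by one observation per
#' line: \code{h<TAB>k<TAB>l<TAB>batch<TAB>I<TAB>sigI} with '.' as decimal
#' separator.  Numeric values are written with 17 significant digits so the
#' round trip through \code{\link{read_unmerged}} is lossless.
#'
#' @param dataset An \code{\link{new_dataset}} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_unmerged <- function(dataset, path) {
  stopifnot(inherits(dataset, "xdataset"))
  cl <- dataset$cell
  hdr <- c(paste("#CELL", paste(.num_fmt(unclass(cl)[1:6]), collapse = " ")),
           paste("#SPACEGROUP", dataset$space_group),
           paste("#DATASET", dataset$label),
           paste("#CRYSTAL", ifelse(is.na(dataset$crystal), "NA",
                                    dataset$crystal)))
  ob <- dataset$observations
  lines <- paste(ob$h, ob$k, ob$l, ob$batch,
                 .num_fmt(ob$intensity), .num_fmt(ob$sigma), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a dataset from a UXT file
#'
#' Parses the dialect written by \code{\link{write_unmerged}}.  Malformed
#' headers, non-integer indices or non-positive sigmas raise an error naming
#' the offending line number.
#'
#' @param path Input file path.
#' @return An \code{\link{new_dataset}} object with \code{path} recorded.
#' @export
read_unmerged <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      parts <- strsplit(sub("^#", "", ln), "[ \t]+")[[1]]
      key <- parts[[1]]
      val <- parts[-1]
      if (key == "CELL") {
        cellv <- suppressWarnings(as.numeric(val))
        if (length(cellv) != 6 || any(is.na(cellv)))
          stop(path, ": line ", i, ": malformed #CELL header")
        hdr$cell <- cellv
      } else if (key == "SPACEGROUP") {
        if (length(val) < 1)
          stop(path, ": line ", i, ": malformed #SPACEGROUP header")
        hdr$sg <- paste(val, collapse = " ")
      } else if (key == "DATASET") {
        hdr$label <- paste(val, collapse = " ")
      } else if (key == "CRYSTAL") {
        hdr$crystal <- paste(val, collapse = " ")
      } else {
        stop(path, ": line ", i, ": unknown header '#", key, "'")
      }
    } else {
      body_start <- i
      break
    }
  }
  if (is.null(hdr$cell)) stop(path, ": missing #CELL header")
  if (is.null(hdr$sg)) stop(path, ": missing #SPACEGROUP header")
  if (is.na(body_start)) stop(path, ": no observation lines")
  body <- lines[body_start:length(lines)]
  body_no <- seq(body_start, length(lines))
  keep <- nzchar(body)
  body <- body[keep]; body_no <- body_no[keep]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6))
    stop(path, ": line ", body_no[which(nf != 6)[1]],
         ": expected 6 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  suppressWarnings({
    hv <- as.numeric(m[, 1]); kv <- as.numeric(m[, 2])
    lv <- as.numeric(m[, 3]); bv <- as.numeric(m[, 4])
    iv <- as.numeric(m[, 5]); sv <- as.numeric(m[, 6])
  })
  bad <- which(is.na(hv) | is.na(kv) | is.na(lv) | is.na(bv) |
               is.na(iv) | is.na(sv))
  if (length(bad))
    stop(path, ": line ", body_no[bad[1]], ": unparsable numeric field")
  bad <- which(hv != round(hv) | kv != round(kv) | lv != round(lv) |
               bv != round(bv))
  if (length(bad))
    stop(path, ": line ", body_no[bad[1]],
         ": indices and batch must be integers")
  bad <- which(sv <= 0)
  if (length(bad))
    stop(path, ": line ", body_no[bad[1]], ": sigma must be > 0")
  obs <- data.frame(h = as.integer(hv), k = as.integer(kv),
                    l = as.integer(lv), batch = as.integer(bv),
                    intensity = iv, sigma = sv)
  new_dataset(obs, cell = do.call(unit_cell, as.list(hdr$cell)),
              space_group = hdr$sg,
              label = if (is.null(hdr$label)) basename(path) else hdr$label,
              crystal = if (is.null(hdr$crystal)) NA_character_ else
                hdr$crystal,
              path = path)
}

# equal reciprocal-volume shell boundaries (in d, decreasing) over [d_lo,
# d_hi] with d_lo > d_hi; returns length n+1 vector
.recip_shell_bounds <- function(d_lo, d_hi, n) {
  if (d_lo <= d_hi) d_lo <- d_hi * (1 + 1e-9)
  s3 <- seq(1 / d_lo^3, 1 / d_hi^3, length.out = n + 1)
  s3^(-1 / 3)
}

# shell index (1 = lowest resolution) for each d given decreasing bounds
.shell_index <- function(d, bounds) {
  n <- length(bounds) - 1
  idx <- findInterval(1 / d^3, 1 / bounds^3, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), n)
}

#' Crude per-dataset resolution estimate
#'
#' Bins the dataset's own observations into 20 equal reciprocal-volume
#' resolution shells and walks from low to high resolution: the estimate is
#' the high-resolution boundary of the outermost shell whose mean I/sigma is
#' at least \code{isd_min}.  If every shell passes this equals the dataset's
#' observed d_min; if no shell passes the observed d_max is returned.  The
#' estimate is deterministic and intentionally coarse -- a per-sweep triage
#' number, not a merging-quality resolution limit.
#'
#' @param dataset An \code{\link{new_dataset}} object.
#' @param n_shells Number of shells (default 20).
#' @param isd_min Mean I/sigma acceptance level per shell (default 1.5).
#' @return Resolution estimate in Angstrom.
#' @export
crude_resolution_estimate <- function(dataset, n_shells = 20,
                                      isd_min = 1.5) {
  stopifnot(inherits(dataset, "xdataset"))
  ob <- dataset$observations
  d <- resolution_of(dataset$cell, ob$h, ob$k, ob$l)
  rng <- range(d)
  if (diff(rng) < 1e-9) return(rng[1])
  bounds <- .recip_shell_bounds(rng[2], rng[1], n_shells)
  idx <- .shell_index(d, bounds)
  isd <- tapply(ob$intensity / ob$sigma, idx, mean)
  pass <- as.integer(names(isd))[isd >= isd_min]
  if (length(pass) == 0) return(rng[2])
  # high-resolution boundary of the outermost passing shell
  bounds[max(pass) + 1]
}

# completeness of one dataset against its own cell/space group at its
# observed d_min (fraction in [0,1])
.dataset_completeness <- function(dataset) {
  ob <- dataset$observations
  d <- resolution_of(dataset$cell, ob$h, ob$k, ob$l)
  d_min <- min(d)
  asu <- map_to_asu(ob$h, ob$k, ob$l, dataset$space_group)
  base <- 2 * max(abs(unlist(asu)), 1) + 3
  n_obs <- length(unique(.hkl_key(asu$h, asu$k, asu$l, base)))
  n_pos <- count_possible_reflections(dataset$cell, dataset$space_group,
                                      d_min)
  min(n_obs / max(n_pos, 1), 1)
}

#' Per-sweep summary table
#'
#' One row per dataset: serial id, source path, observation count, number of
#' distinct batches, the crude resolution estimate and an estimated
#' completeness fraction (unique reflections observed over those possible at
#' the sweep's own d_min).  This is the table that lets complete sweeps be
#' triaged from partial ones.
#'
#' @param datasets List of \code{\link{new_dataset}} objects.
#' @return Data.frame with columns \code{id}, \code{path}, \code{n_obs},
#'   \code{n_batches}, \code{resolution_estimate},
#'   \code{completeness_estimate}.
#' @export
sweep_summary <- function(datasets) {
  rows <- lapply(datasets, function(ds) {
    data.frame(id = ds$id, path = ds$path,
               n_obs = nrow(ds$observations),
               n_batches = length(unique(ds$observations$batch)),
               resolution_estimate = crude_resolution_estimate(ds),
               completeness_estimate = .dataset_completeness(ds))
  })
  do.call(rbind, rows)
}

#' Write the per-sweep summary table
#'
#' @param summary Data.frame from \code{\link{sweep_summary}}.
#' @param path Output TSV path (conventionally
#'   \code{"final_list_of_files.tsv"}).
#' @return \code{path}, invisibly.
#' @export
write_sweep_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
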