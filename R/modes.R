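# Execution modes: analysis / dendrogram-only, synthesis (merge one
# cluster), combination (merge an arbitrary serial list), and the two
# combination-mode variants -- greedy dataset filtering and cyclic
# trailing-image pruning -- plus manual batch exclusion.

.as_datasets <- function(inputs, dendrogram_only = FALSE) {
  if (length(inputs) == 0) stop("no input datasets")
  if (inherits(inputs, "xdataset")) inputs <- list(inputs)
  if (is.character(inputs)) {
    datasets <- list()
    failures <- character(0)
    for (p in inputs) {
      ds <- tryCatch(read_unmerged(p), error = function(e)
        conditionMessage(e))
      if (is.character(ds)) failures <- c(failures, ds)
      else datasets <- c(datasets, list(ds))
    }
    if (length(failures)) {
      if (dendrogram_only) {
        warning("skipping unreadable dataset file(s):\n  ",
                paste(failures, collapse = "\n  "))
      } else {
        stop("unreadable dataset file(s):\n  ",
             paste(failures, collapse = "\n  "))
      }
    }
    return(datasets)
  }
  stopifnot(all(vapply(inputs, inherits, logical(1), "xdataset")))
  inputs
}

#' Analysis mode: validate, summarize and cluster a set of datasets
#'
#' Reads every input sweep, assigns serial numbers 1..N in input order (any
#' previous numbering is lost -- each run renumbers), builds the
#' symmetry-aware cell descriptors, runs hierarchical clustering with aLCV
#' annotation and cluster enumeration, and produces the per-sweep summary
#' table.  In full analysis mode an unreadable file aborts the run listing
#' the failures; in dendrogram-only mode it is skipped with a warning and
#' the remaining sweeps are clustered (a fast triage pass for spotting
#' outliers before any merging).
#'
#' @param inputs Character vector of UXT file paths, or a list of
#'   \code{\link{new_dataset}} objects.
#' @param dendrogram_only If TRUE, tolerate unreadable files and skip the
#'   sweep-summary computation.
#' @param outdir Optional output directory; when given, writes
#'   \code{final_list_of_files.tsv}, \code{dendrogram.nwk},
#'   \code{dendrogram.txt} and \code{clusters.json} there.
#' @param linkage,scaling Clustering options, see \code{\link{hca}} and
#'   \code{\link{build_descriptors}}.
#' @return An object of class \code{"mx_analysis"}: list with
#'   \code{datasets} (serials assigned), \code{dendrogram} (annotated),
#'   \code{cluster_table} and \code{sweeps} (NULL in dendrogram-only mode).
#' @export
analysis_mode <- function(inputs, dendrogram_only = FALSE, outdir = NULL,
                          linkage = "ward", scaling = "mean") {
  datasets <- .as_datasets(inputs, dendrogram_only)
  if (length(datasets) < 2)
    stop("analysis needs at least 2 readable datasets")
  for (i in seq_along(datasets)) datasets[[i]]$id <- i
  names(datasets) <- as.character(seq_along(datasets))
  sgs <- unique(vapply(datasets, `[[`, character(1), "space_group"))
  if (length(sgs) > 1)
    warning("datasets declare different space groups: ",
            paste(sgs, collapse = ", "))
  desc <- build_descriptors(datasets, scaling = scaling)
  dend <- annotate_alcv(hca(desc, linkage = linkage), datasets)
  ct <- enumerate_clusters(dend)
  sweeps <- if (dendrogram_only) NULL else sweep_summary(datasets)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sweeps))
      write_sweep_summary(sweeps, file.path(outdir,
                                            "final_list_of_files.tsv"))
    as_newick(dend, file.path(outdir, "dendrogram.nwk"))
    writeLines(render_dendrogram(dend), file.path(outdir, "dendrogram.txt"))
    cluster_table_json(ct, file.path(outdir, "clusters.json"))
  }
  structure(list(datasets = datasets, dendrogram = dend,
                 cluster_table = ct, sweeps = sweeps),
            class = "mx_analysis")
}

#' @export
print.mx_analysis <- function(x, ...) {
  cat(sprintf("analysis of %d datasets -> %d clusters\n",
              length(x$datasets), nrow(x$cluster_table)))
  invisible(x)
}

.pick_serials <- function(analysis, serials) {
  ids <- vapply(analysis$datasets, `[[`, integer(1), "id")
  bad <- setdiff(serials, ids)
  if (length(bad))
    stop("unknown dataset serial(s) ", paste(bad, collapse = ", "),
         "; valid range 1..", max(ids))
  analysis$datasets[match(serials, ids)]
}

#' Synthesis mode: scale and merge one numbered cluster
#'
#' @param analysis A prior \code{\link{analysis_mode}} result.
#' @param cluster_number Cluster number in 1..N-1.
#' @param resolution_max Optional high-resolution cutoff (Angstrom).
#' @param n_shells Shells for statistics.
#' @return A \code{\link{compute_stats}} object for the cluster's members.
#' @export
synthesis_mode <- function(analysis, cluster_number, resolution_max = NULL,
                           n_shells = 10) {
  stopifnot(inherits(analysis, "mx_analysis"))
  members <- cluster_members(analysis$cluster_table, cluster_number)
  combination_mode(analysis, as.integer(members), resolution_max, n_shells)
}

#' Combination mode: scale and merge an arbitrary list of dataset serials
#'
#' Merges exactly the listed datasets (in serial order, so the result is
#' independent of the order given); a single serial yields the statistics of
#' that dataset alone (a single-crystal dataset's quality report).
#'
#' @param analysis A prior \code{\link{analysis_mode}} result, or a plain
#'   list of datasets with ids assigned.
#' @param serials Integer dataset serial numbers.
#' @param resolution_max Optional high-resolution cutoff (Angstrom).
#' @param n_shells Shells for statistics.
#' @param batch_exclusions Optional exclusion map applied before scaling,
#'   see \code{\link{apply_batch_exclusions}}.
#' @return A \code{\link{compute_stats}} object.
#' @export
combination_mode <- function(analysis, serials, resolution_max = NULL,
                             n_shells = 10, batch_exclusions = NULL) {
  if (inherits(analysis, "mx_analysis")) {
    if (length(serials) == 0) stop("empty serial list")
    datasets <- .pick_serials(analysis, sort(unique(as.integer(serials))))
  } else {
    datasets <- .as_datasets(analysis)
    if (length(serials) == 0) stop("empty serial list")
    ids <- vapply(datasets, `[[`, integer(1), "id")
    datasets <- datasets[match(sort(unique(as.integer(serials))), ids)]
    if (any(vapply(datasets, is.null, logical(1))))
      stop("unknown dataset serial in ", paste(serials, collapse = ", "))
  }
  if (!is.null(batch_exclusions))
    datasets <- apply_batch_exclusions(datasets, batch_exclusions)
  model <- fit_scales(datasets, resolution_max)
  merged <- merge_datasets(datasets, model, resolution_max)
  compute_stats(datasets, model, merged, resolution_max, n_shells)
}

#' Drop observations in excluded batch ranges
#'
#' Manual exclusion of image ranges (e.g. radiation-damaged sweep tails)
#' before scaling.  Ranges are inclusive, 1-based batch numbers.  A dataset
#' whose observations are all excluded is dropped with a warning.
#'
#' @param datasets List of \code{\link{new_dataset}} objects.
#' @param exclusions Named list: dataset serial (as character) or label ->
#'   list of \code{c(first, last)} ranges (a single range may be given
#'   unnested).
#' @return The filtered dataset list.
#' @export
apply_batch_exclusions <- function(datasets, exclusions) {
  if (length(exclusions) == 0) return(datasets)
  keys <- vapply(datasets, function(ds)
    if (!is.na(ds$id)) as.character(ds$id) else ds$label, character(1))
  labels <- vapply(datasets, `[[`, character(1), "label")
  keep <- rep(TRUE, length(datasets))
  for (nm in names(exclusions)) {
    idx <- which(keys == nm | labels == nm)
    if (length(idx) == 0) next
    ranges <- exclusions[[nm]]
    if (!is.list(ranges)) ranges <- list(ranges)
    ds <- datasets[[idx]]
    drop <- rep(FALSE, nrow(ds$observations))
    for (r in ranges) {
      if (length(r) != 2 || r[1] > r[2])
        stop("malformed batch range for dataset ", nm, ": ",
             paste(r, collapse = "-"),
             " (need first <= last)")
      drop <- drop | (ds$observations$batch >= r[1] &
                      ds$observations$batch <= r[2])
    }
    if (all(drop)) {
      warning("dataset ", nm, " has no observations left after batch ",
              "exclusion; dropping it")
      keep[[idx]] <- FALSE
    } else {
      ob <- ds$observations[!drop, , drop = FALSE]
      datasets[[idx]] <- new_dataset(ob, ds$cell, ds$space_group,
                                     label = ds$label,
                                     crystal = ds$crystal, id = ds$id,
                                     path = ds$path)
    }
  }
  datasets[keep]
}

.trial_stats <- function(analysis, serials, resolution_max, n_shells,
                         batch_exclusions) {
  combination_mode(analysis, serials, resolution_max, n_shells,
                   batch_exclusions = batch_exclusions)
}

#' Greedy dataset-filtering variant of combination mode
#'
#' Starting from a group of datasets, one dataset at a time is discarded
#' until convergence towards a low Rmeas: each round evaluates the removal
#' of every remaining dataset (full re-scale and re-merge without it) and
#' commits the removal with the lowest trial Rmeas, provided it improves the
#' current Rmeas by more than the \code{min_improvement} fraction and trial
#' completeness stays at or above the threshold.  The loop stops when no
#' admissible removal improves Rmeas or only two datasets remain.  Ties
#' break towards the smaller serial.  If the starting completeness is
#' already below the threshold a warning is issued and filtering proceeds
#' (removals must still not go below the threshold).
#'
#' The improvement margin exists because trial Rmeas values fluctuate at the
#' percent level from sampling alone (removing data re-partitions the
#' unique-reflection sums), while genuine non-isomorphism effects are tens
#' of percent; a plain strict descent would slowly strip clean data.
#' \code{min_improvement = 0} recovers strict descent.
#'
#' @param analysis A prior \code{\link{analysis_mode}} result (or dataset
#'   list with ids).
#' @param start_serials Starting dataset serials (>= 2).
#' @param completeness_threshold Completeness floor in percent, in (0, 100].
#' @param resolution_max Optional high-resolution cutoff (Angstrom).
#' @param n_shells Shells for statistics.
#' @param min_improvement Minimum relative Rmeas improvement for a commit
#'   (default 0.05).
#' @return An object of class \code{"combination_result"}: final serials,
#'   removed serials, stats before/after, and an audit trail recording every
#'   trial of every round.
#' @export
filtering_variant <- function(analysis, start_serials,
                              completeness_threshold = 95,
                              resolution_max = NULL, n_shells = 10,
                              min_improvement = 0.05) {
  serials <- sort(unique(as.integer(start_serials)))
  if (length(serials) < 2) stop("filtering needs at least 2 datasets")
  if (completeness_threshold <= 0 || completeness_threshold > 100)
    stop("completeness_threshold must be in (0, 100]")
  current <- .trial_stats(analysis, serials, resolution_max, n_shells, NULL)
  initial <- current
  if (current$overall$completeness < completeness_threshold)
    warning(sprintf(
      "starting completeness %.1f%% is below the %.1f%% threshold",
      current$overall$completeness, completeness_threshold))
  audit <- list()
  removed <- integer(0)
  repeat {
    if (length(serials) <= 2) break
    trials <- lapply(serials, function(s) {
      st <- .trial_stats(analysis, setdiff(serials, s), resolution_max,
                         n_shells, NULL)
      list(serial = s, rmeas = st$overall$rmeas,
           completeness = st$overall$completeness, stats = st)
    })
    tr_df <- data.frame(
      serial = vapply(trials, `[[`, integer(1), "serial"),
      rmeas = vapply(trials, `[[`, numeric(1), "rmeas"),
      completeness = vapply(trials, `[[`, numeric(1), "completeness"))
    tr_df$admissible <- !is.na(tr_df$rmeas) &
      tr_df$rmeas < current$overall$rmeas * (1 - min_improvement) &
      tr_df$completeness >= completeness_threshold
    audit[[length(audit) + 1]] <-
      list(action = "filter_round", remaining = serials, trials = tr_df)
    ok <- which(tr_df$admissible)
    if (length(ok) == 0) break
    best <- ok[order(tr_df$rmeas[ok], tr_df$serial[ok])][1]
    s_rm <- tr_df$serial[[best]]
    serials <- setdiff(serials, s_rm)
    removed <- c(removed, s_rm)
    current <- trials[[best]]$stats
    audit[[length(audit)]]$committed <- s_rm
  }
  structure(list(final_serials = serials, removed_serials = removed,
                 removed_batches = list(),
                 stats_initial = initial, stats_final = current,
                 completeness_threshold = completeness_threshold,
                 resolution_max = resolution_max, audit = audit),
            class = "combination_result")
}

#' Cyclic trailing-image pruning variant of combination mode
#'
#' Automated exclusion of sweep tails biased by radiation damage.  Each
#' round trial-removes the trailing \code{chunk} images of every dataset
#' still prunable and commits the single trial with the lowest Rmeas,
#' provided it improves Rmeas by more than the \code{min_improvement}
#' fraction (see \code{\link{filtering_variant}} for why a margin is
#' needed) and keeps completeness at or above the threshold.  Datasets are
#' visited cyclically: within a sweep no dataset is pruned a second time
#' before every other prunable dataset has been tried once.  The loop stops
#' when no admissible trial improves Rmeas; it may remove nothing.  A
#' dataset is never pruned below \code{chunk + 1} remaining images.
#'
#' @inheritParams filtering_variant
#' @param serials Dataset serials to merge.
#' @param chunk Number of trailing images removed per committed prune
#'   (default 5; 1 recovers per-image pruning).
#' @return A \code{"combination_result"}; \code{removed_batches} maps serial
#'   -> excluded (first, last) batch ranges.
#' @export
pruning_variant <- function(analysis, serials, completeness_threshold = 95,
                            chunk = 5, resolution_max = NULL,
                            n_shells = 10, min_improvement = 0.05) {
  serials <- sort(unique(as.integer(serials)))
  if (chunk < 1) stop("chunk must be >= 1")
  datasets <- if (inherits(analysis, "mx_analysis"))
    .pick_serials(analysis, serials) else .as_datasets(analysis)
  batch_max <- stats::setNames(
    vapply(datasets, function(ds) ds$batch_range[[2]], numeric(1)),
    as.character(serials))
  tail_cut <- stats::setNames(rep(Inf, length(serials)),
                              as.character(serials))  # first excluded batch
  excl_map <- function() {
    out <- list()
    for (s in as.character(serials)) {
      if (is.finite(tail_cut[[s]]))
        out[[s]] <- list(c(tail_cut[[s]], batch_max[[s]]))
    }
    out
  }
  current <- .trial_stats(analysis, serials, resolution_max, n_shells, NULL)
  initial <- current
  audit <- list()
  pruned_this_sweep <- character(0)
  repeat {
    prunable <- as.character(serials)[vapply(as.character(serials),
      function(s) {
        first_ex <- min(tail_cut[[s]], batch_max[[s]] + 1)
        first_ex - chunk >= 2       # keep at least one image
      }, logical(1))]
    candidates <- setdiff(prunable, pruned_this_sweep)
    if (length(candidates) == 0) {
      if (length(pruned_this_sweep) == 0) break
      pruned_this_sweep <- character(0)
      next
    }
    trials <- lapply(candidates, function(s) {
      tc <- tail_cut
      first_ex <- min(tc[[s]], batch_max[[s]] + 1)
      tc[[s]] <- first_ex - chunk
      ex <- list()
      for (q in as.character(serials)) {
        if (is.finite(tc[[q]]))
          ex[[q]] <- list(c(tc[[q]], batch_max[[q]]))
      }
      st <- .trial_stats(analysis, serials, resolution_max, n_shells, ex)
      list(serial = s, tail_cut = tc, rmeas = st$overall$rmeas,
           completeness = st$overall$completeness, stats = st)
    })
    tr_df <- data.frame(
      serial = vapply(trials, `[[`, character(1), "serial"),
      rmeas = vapply(trials, `[[`, numeric(1), "rmeas"),
      completeness = vapply(trials, `[[`, numeric(1), "completeness"))
    tr_df$admissible <- !is.na(tr_df$rmeas) &
      tr_df$rmeas < current$overall$rmeas * (1 - min_improvement) &
      tr_df$completeness >= completeness_threshold
    audit[[length(audit) + 1]] <-
      list(action = "prune_round", tail_cut = tail_cut, trials = tr_df)
    ok <- which(tr_df$admissible)
    if (length(ok) == 0) {
      if (length(pruned_this_sweep) == 0) break
      pruned_this_sweep <- character(0)
      next
    }
    best <- ok[order(tr_df$rmeas[ok],
                     as.integer(tr_df$serial[ok]))][1]
    s_pr <- tr_df$serial[[best]]
    tail_cut <- trials[[best]]$tail_cut
    current <- trials[[best]]$stats
    pruned_this_sweep <- c(pruned_this_sweep, s_pr)
    audit[[length(audit)]]$committed <- s_pr
  }
  structure(list(final_serials = serials, removed_serials = integer(0),
                 removed_batches = excl_map(),
                 stats_initial = initial, stats_final = current,
                 completeness_threshold = completeness_threshold,
                 resolution_max = resolution_max, chunk = chunk,
                 audit = audit),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf(paste0(
    "combination result: %d datasets kept (removed: %s)\n",
    "  pruned batch ranges: %s\n",
    "  Rmeas %.4g -> %.4g, completeness %.1f%% -> %.1f%%\n"),
    length(x$final_serials),
    if (length(x$removed_serials)) paste(x$removed_serials, collapse = ", ")
    else "none",
    if (length(x$removed_batches))
      paste(vapply(names(x$removed_batches), function(s)
        sprintf("%s:%d-%d", s, x$removed_batches[[s]][[1]][1],
                x$removed_batches[[s]][[1]][2]), character(1)),
        collapse = ", ")
    else "none",
    x$stats_initial$overall$rmeas, x$stats_final$overall$rmeas,
    x$stats_initial$overall$completeness,
    x$stats_final$overall$completeness))
  invisible(x)
}

#' Replay a combination result
#'
#' Re-runs combination mode on the recorded final member list and batch
#' exclusions; by construction this reproduces the final statistics exactly.
#'
#' @param analysis The analysis the result came from.
#' @param result A \code{"combination_result"}.
#' @param n_shells Shells for statistics.
#' @return A \code{\link{compute_stats}} object.
#' @export
replay_combination <- function(analysis, result, n_shells = 10) {
  combination_mode(analysis, result$final_serials, result$resolution_max,
                   n_shells, batch_exclusions = result$removed_batches)
}

#' Write a combination result's audit trail as JSON
#'
#' @param result A \code{"combination_result"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_audit_trail <- function(result, path) {
  steps <- lapply(result$audit, function(st) {
    out <- list(action = st$action, trials = st$trials)
    if (!is.null(st$committed)) out$committed <- st$committed
    if (!is.null(st$remaining)) out$remaining <- st$remaining
    out
  })
  jsonlite::write_json(
    list(final_serials = result$final_serials,
         removed_serials = result$removed_serials,
         removed_batches = result$removed_batches,
         completeness_threshold = result$completeness_threshold,
         rmeas_initial = result$stats_initial$overall$rmeas,
         rmeas_final = result$stats_final$overall$rmeas,
         steps = steps),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Parse a keyword file
#'
#' One directive per line, case-insensitive: \code{RESO HIGH <d>},
#' \code{BATCH EXCLUDE <serial> <first> <last>}, \code{COMPLETENESS <pct>},
#' \code{CHUNK <n>}.  \code{#} starts a comment.
#'
#' @param path Keyword file path.
#' @return List with \code{resolution_max}, \code{completeness},
#'   \code{chunk}, \code{batch_exclusions} (possibly NULL/empty).
#' @export
read_keywords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list(resolution_max = NULL, completeness = NULL, chunk = NULL,
              batch_exclusions = list())
  for (ln in lines) {
    tok <- strsplit(toupper(ln), "[ \t]+")[[1]]
    raw <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) >= 3 && tok[1] == "RESO" && tok[2] == "HIGH") {
      out$resolution_max <- as.numeric(raw[3])
    } else if (length(tok) >= 5 && tok[1] == "BATCH" &&
               tok[2] == "EXCLUDE") {
      s <- raw[3]; r <- as.numeric(raw[4:5])
      if (any(is.na(r)) || r[1] > r[2])
        stop("malformed BATCH EXCLUDE directive: ", ln)
      out$batch_exclusions[[s]] <-
        c(out$batch_exclusions[[s]], list(r))
    } else if (length(tok) >= 2 && tok[1] == "COMPLETENESS") {
      out$completeness <- as.numeric(raw[2])
    } else if (length(tok) >= 2 && tok[1] == "CHUNK") {
      out$chunk <- as.numeric(raw[2])
    } else {
      stop("unknown keyword directive: ", ln)
    }
  }
  out
}
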