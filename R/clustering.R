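# Symmetry-aware descriptor construction and hierarchical cluster analysis
# of unit cells, with aLCV-annotated dendrograms.

.extract_cells <- function(x) {
  if (inherits(x, "xdataset")) x <- list(x)
  cells <- lapply(x, function(el) {
    if (inherits(el, "xdataset")) el$cell else as_unit_cell(el)
  })
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(seq_along(x), function(i) {
      el <- x[[i]]
      if (inherits(el, "xdataset") && !is.na(el$id)) as.character(el$id)
      else if (inherits(el, "xdataset")) el$label
      else as.character(i)
    }, character(1))
  }
  names(cells) <- ids
  cells
}

.extract_systems <- function(x) {
  if (inherits(x, "xdataset")) x <- list(x)
  syss <- vapply(x, function(el) {
    if (inherits(el, "xdataset")) spacegroup_info(el$space_group)$system
    else NA_character_
  }, character(1))
  syss[!is.na(syss)]
}

#' Build the cell-descriptor matrix for clustering
#'
#' Datasets are turned into points in descriptor space using the independent
#' cell parameters of the declared crystal system: all six for triclinic,
#' (a, b, c, beta) for monoclinic, (a, b, c) for orthorhombic, (a, c) for
#' tetragonal/trigonal/hexagonal and a alone for cubic.  With
#' \code{scaling = "mean"} every column is divided by its mean, so lengths
#' and angles of different magnitudes weigh comparably and descriptors are
#' dimensionless.
#'
#' @param datasets List of \code{\link{new_dataset}} objects or
#'   \code{\link{unit_cell}}s (optionally named with dataset ids).
#' @param crystal_system Crystal system; defaults to the system of the
#'   datasets' space groups (which must agree).
#' @param scaling \code{"mean"} (default) or \code{"none"}.
#' @return A numeric matrix (rows = datasets, columns = free parameters) of
#'   class \code{"descriptor_matrix"}, with attributes \code{system},
#'   \code{scaling} and \code{scale_factors}.
#' @export
build_descriptors <- function(datasets, crystal_system = NULL,
                              scaling = c("mean", "none")) {
  scaling <- match.arg(scaling)
  cells <- .extract_cells(datasets)
  if (length(cells) < 2) stop("need at least 2 datasets")
  if (is.null(crystal_system)) {
    syss <- unique(.extract_systems(datasets))
    if (length(syss) == 0)
      stop("crystal_system must be given when clustering bare cells")
    if (length(syss) > 1)
      stop("datasets span multiple crystal systems: ",
           paste(syss, collapse = ", "))
    crystal_system <- syss
  }
  pars <- free_cell_parameters(crystal_system)
  M <- t(vapply(cells, function(cl) unclass(cl)[pars], numeric(length(pars))))
  if (length(pars) == 1) {
    M <- matrix(M, ncol = 1)
  }
  dimnames(M) <- list(names(cells), pars)
  fac <- rep(1, ncol(M))
  if (scaling == "mean") {
    fac <- colMeans(M)
    M <- sweep(M, 2, fac, "/")
  }
  structure(M, system = crystal_system, scaling = scaling,
            scale_factors = fac, class = c("descriptor_matrix", "matrix"))
}

#' Hierarchical cluster analysis of cell descriptors
#'
#' Agglomerative clustering with Euclidean distances; Ward linkage by
#' default (\code{stats::hclust} method \code{"ward.D2"}), with complete and
#' average linkage as options.  The result is a binary merge tree over the
#' datasets: N leaves, N-1 internal nodes, each node carrying its merge
#' height (dimensionless, in descriptor units), member leaves and -- after
#' \code{\link{annotate_alcv}} -- the aLCV of its member cells.
#'
#' @param descriptors A \code{\link{build_descriptors}} matrix.
#' @param linkage \code{"ward"} (default), \code{"complete"} or
#'   \code{"average"}.
#' @return An object of class \code{"cell_dendrogram"}.
#' @export
hca <- function(descriptors, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(descriptors) < 2) stop("need at least 2 datasets to cluster")
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  hc <- stats::hclust(stats::dist(unclass(descriptors)), method = method)
  labels <- rownames(descriptors)
  n <- nrow(descriptors)
  nodes <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    ch <- hc$merge[i, ]
    members <- integer(0)
    for (c_ in ch) {
      members <- c(members,
                   if (c_ < 0) -c_ else nodes[[c_]]$members)
    }
    nodes[[i]] <- list(children = ch, members = sort(members),
                       height = hc$height[i], alcv = NA_real_)
  }
  structure(list(hc = hc, labels = labels, nodes = nodes,
                 linkage = linkage),
            class = "cell_dendrogram")
}

#' @export
print.cell_dendrogram <- function(x, ...) {
  ann <- if (all(is.na(vapply(x$nodes, `[[`, numeric(1), "alcv"))))
    "unannotated" else "aLCV-annotated"
  cat(sprintf("cell dendrogram: %d datasets, %d clusters (%s linkage, %s)\n",
              length(x$labels), length(x$nodes), x$linkage, ann))
  invisible(x)
}

#' Annotate a dendrogram with per-node aLCV
#'
#' Sets each internal node's aLCV to the group aLCV (maximum pairwise value)
#' of its member cells; leaves have aLCV 0 by definition.
#'
#' @param dendrogram A \code{\link{hca}} result.
#' @param cells List of \code{\link{unit_cell}}s in leaf order (one per
#'   dataset), or the dataset list itself.
#' @return The dendrogram with node \code{alcv} fields filled in.
#' @export
annotate_alcv <- function(dendrogram, cells) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  cells <- .extract_cells(cells)
  if (length(cells) != length(dendrogram$labels))
    stop("need exactly one cell per dendrogram leaf")
  M <- alcv_matrix(cells)
  dendrogram$nodes <- lapply(dendrogram$nodes, function(nd) {
    mem <- nd$members
    nd$alcv <- max(M[mem, mem])
    nd
  })
  dendrogram$alcv_matrix <- M
  dendrogram
}

.node_member_labels <- function(dend, i) {
  dend$labels[dend$nodes[[i]]$members]
}

# deterministic cluster numbering: by (height, size, sorted member labels)
.cluster_order <- function(dend) {
  hts <- vapply(dend$nodes, `[[`, numeric(1), "height")
  szs <- vapply(dend$nodes, function(nd) length(nd$members), integer(1))
  keys <- vapply(seq_along(dend$nodes), function(i)
    paste(sort(.node_member_labels(dend, i)), collapse = ","), character(1))
  order(hts, szs, keys)
}

#' Enumerate the clusters of a dendrogram
#'
#' Internal nodes are numbered 1..N-1 in order of increasing merge height
#' (ties broken by smaller member count, then lexicographic member ids); the
#' highest-numbered cluster is the root containing every dataset.
#'
#' @param dendrogram A (preferably \code{\link{annotate_alcv}}-annotated)
#'   dendrogram.
#' @return Data.frame of class \code{"cluster_table"}: columns
#'   \code{cluster}, \code{n_datasets}, \code{height}, \code{alcv},
#'   \code{members} (comma-separated dataset ids); the per-cluster member id
#'   vectors are attached as the \code{"member_list"} attribute.
#' @export
enumerate_clusters <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  ord <- .cluster_order(dendrogram)
  rows <- lapply(seq_along(ord), function(num) {
    i <- ord[[num]]
    nd <- dendrogram$nodes[[i]]
    labs <- .node_member_labels(dendrogram, i)
    data.frame(cluster = num, n_datasets = length(nd$members),
               height = nd$height, alcv = nd$alcv,
               members = paste(labs, collapse = ","))
  })
  out <- do.call(rbind, rows)
  attr(out, "member_list") <-
    lapply(ord, function(i) .node_member_labels(dendrogram, i))
  attr(out, "node_index") <- ord
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Members of a numbered cluster
#'
#' @param cluster_table A \code{\link{enumerate_clusters}} table.
#' @param cluster Cluster number in 1..N-1.
#' @return Character vector of member dataset ids.
#' @export
cluster_members <- function(cluster_table, cluster) {
  ml <- attr(cluster_table, "member_list")
  if (!is.numeric(cluster) || cluster < 1 || cluster > length(ml))
    stop("cluster number must be in 1..", length(ml))
  ml[[cluster]]
}

#' Flag non-isomorphous datasets from an annotated dendrogram
#'
#' A dataset is flagged as an outlier when its first merge into the tree (the
#' smallest cluster containing it) happens at a node whose aLCV exceeds the
#' threshold -- i.e. it cannot join any other dataset without breaking cell
#' isomorphism at the given level.  This is an explicit automation of the
#' visual outlier triage usually done on the dendrogram.
#'
#' @param dendrogram An annotated \code{\link{cell_dendrogram}} (or pass
#'   \code{cells} to annotate on the fly).
#' @param cells Optional cells/datasets for annotation.
#' @param alcv_threshold Threshold in Angstrom, > 0.
#' @return Character vector of flagged dataset ids (possibly empty).
#' @export
flag_outliers <- function(dendrogram, cells = NULL, alcv_threshold) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  if (!is.numeric(alcv_threshold) || alcv_threshold <= 0)
    stop("alcv_threshold must be > 0")
  if (!is.null(cells)) dendrogram <- annotate_alcv(dendrogram, cells)
  alcvs <- vapply(dendrogram$nodes, `[[`, numeric(1), "alcv")
  if (any(is.na(alcvs)))
    stop("dendrogram is not aLCV-annotated; call annotate_alcv() first")
  n <- length(dendrogram$labels)
  flagged <- character(0)
  for (leaf in seq_len(n)) {
    first <- which(apply(dendrogram$hc$merge == -leaf, 1, any))[1]
    if (alcvs[[first]] > alcv_threshold)
      flagged <- c(flagged, dendrogram$labels[[leaf]])
  }
  flagged
}

.fmt_alcv <- function(x) {
  if (is.na(x)) "?" else sprintf("%.4g", x)
}

#' Render a dendrogram as text (or image)
#'
#' The text rendering is a stable, diffable ASCII tree; every internal node
#' is labelled with its cluster number and aLCV.  With \code{style =
#' "height"} nodes show their merge height; with \code{style = "level"}
#' nodes show their level, defined as the number of member datasets, so all
#' clusters of equal size sit at the same level.  With \code{format =
#' "image"} a PNG of the classical height dendrogram is written to
#' \code{file}.
#'
#' @param dendrogram An annotated dendrogram.
#' @param style \code{"height"} or \code{"level"}.
#' @param format \code{"text"} (default) or \code{"image"}.
#' @param file Output path; required for \code{format = "image"}, optional
#'   for text.
#' @return For text: character vector of lines (invisibly written to
#'   \code{file} if given).  For image: \code{file}.
#' @export
render_dendrogram <- function(dendrogram, style = c("height", "level"),
                              format = c("text", "image"), file = NULL) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  style <- match.arg(style)
  format <- match.arg(format)
  if (format == "image") {
    if (is.null(file)) stop("file is required for image rendering")
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    graphics::plot(dendrogram$hc, labels = dendrogram$labels,
                   main = "cell dendrogram", xlab = "", sub = "")
    return(invisible(file))
  }
  ct <- enumerate_clusters(dendrogram)
  node_num <- integer(length(dendrogram$nodes))
  node_num[attr(ct, "node_index")] <- ct$cluster
  root <- length(dendrogram$nodes)
  lines <- character(0)
  descend <- function(id, prefix, tail, is_root = FALSE) {
    branch <- if (is_root) "" else if (tail) "`-- " else "+-- "
    child_prefix <- paste0(prefix,
                           if (is_root) "" else if (tail) "    " else "|   ")
    if (id < 0) {
      lines <<- c(lines, paste0(prefix, branch, dendrogram$labels[[-id]]))
      return(invisible())
    }
    nd <- dendrogram$nodes[[id]]
    pos <- if (style == "height") sprintf("h=%.4g", nd$height)
           else sprintf("level=%d", length(nd$members))
    lines <<- c(lines,
                paste0(prefix, branch,
                       sprintf("cluster %d [%s, aLCV=%s A, n=%d]",
                               node_num[[id]], pos, .fmt_alcv(nd$alcv),
                               length(nd$members))))
    ch <- nd$children
    descend(ch[[1]], child_prefix, FALSE)
    descend(ch[[2]], child_prefix, TRUE)
  }
  descend(root, "", TRUE, is_root = TRUE)
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' Serialize a dendrogram to Newick
#'
#' Internal nodes are labelled \code{cluster<N>_<aLCV>}; branch lengths are
#' merge-height differences.
#'
#' @param dendrogram An annotated dendrogram.
#' @param file Optional output path.
#' @return The Newick string.
#' @export
as_newick <- function(dendrogram, file = NULL) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  ct <- enumerate_clusters(dendrogram)
  node_num <- integer(length(dendrogram$nodes))
  node_num[attr(ct, "node_index")] <- ct$cluster
  build <- function(id, parent_h) {
    if (id < 0) {
      leaf <- dendrogram$labels[[-id]]
      return(sprintf("%s:%.6g", gsub("[,:;() ]", "_", leaf), parent_h))
    }
    nd <- dendrogram$nodes[[id]]
    lab <- sprintf("cluster%d_%s", node_num[[id]], .fmt_alcv(nd$alcv))
    sprintf("(%s,%s)%s:%.6g",
            build(nd$children[[1]], nd$height),
            build(nd$children[[2]], nd$height),
            lab, max(parent_h - nd$height, 0))
  }
  root <- length(dendrogram$nodes)
  nwk <- paste0(build(root, dendrogram$nodes[[root]]$height), ";")
  if (!is.null(file)) writeLines(nwk, file)
  nwk
}

#' Serialize a cluster table to JSON
#'
#' @param cluster_table A \code{\link{enumerate_clusters}} table.
#' @param file Optional output path.
#' @return JSON string (invisibly written to \code{file} if given).
#' @export
cluster_table_json <- function(cluster_table, file = NULL) {
  recs <- lapply(seq_len(nrow(cluster_table)), function(i) {
    list(cluster = cluster_table$cluster[[i]],
         n_datasets = cluster_table$n_datasets[[i]],
         height = cluster_table$height[[i]],
         alcv = cluster_table$alcv[[i]],
         members = as.list(cluster_members(cluster_table,
                                           cluster_table$cluster[[i]])))
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) writeLines(js, file)
  invisible(js)
}
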