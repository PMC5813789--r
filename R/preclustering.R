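# Pre-clustering by experimental conditions: partition datasets into groups
# with identical preparation (growth conditions, cryoprotection, dehydration,
# co-crystallisation, heavy atom) before any cell-based clustering.

.COND_FIELDS <- c("BC", "CC", "DH", "CO", "HA")

#' Read a per-dataset conditions table
#'
#' The conditions table is a TSV with a header row naming at least
#' \code{dataset_id}, \code{BC} (base/growth condition code), \code{CC}
#' (cryogenic condition code), \code{DH} (dehydration protocol or
#' \code{"no"}), \code{CO} (\code{yes}/\code{no} co-crystallisation flag)
#' and \code{HA} (heavy-atom species or \code{"no"}); a \code{crystal_id}
#' column and any extra columns are preserved but ignored by the grouping.
#' Lines starting with \code{#} are comments.
#'
#' @param path TSV file path.
#' @return Data.frame of conditions records.
#' @export
read_conditions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  need <- c("dataset_id", .COND_FIELDS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": conditions table lacks column(s): ",
         paste(miss, collapse = ", "))
  validate_conditions(df)
  df
}

validate_conditions <- function(records) {
  if (any(duplicated(records$dataset_id)))
    stop("duplicate dataset_id in conditions records: ",
         paste(unique(records$dataset_id[duplicated(records$dataset_id)]),
               collapse = ", "))
  for (f in .COND_FIELDS) {
    if (any(!nzchar(records[[f]])))
      stop("empty values in conditions column ", f)
  }
  if (!all(records$CO %in% c("yes", "no")))
    stop("CO must be 'yes' or 'no'")
  invisible(records)
}

#' Group datasets by experimental conditions
#'
#' One group per distinct combination of (BC, CC, DH, CO, HA).  Serial
#' numbers (SN) are assigned in order of first appearance of each
#' combination in the input; NC counts the member datasets.
#'
#' @param records Conditions data.frame (see \code{\link{read_conditions}}).
#' @return Data.frame with columns BC, CC, DH, CO, HA, NC, SN; member
#'   dataset-id vectors attached as the \code{"member_list"} attribute
#'   (named by SN).
#' @export
group_by_conditions <- function(records) {
  records <- validate_conditions(as.data.frame(records))
  if (nrow(records) == 0) {
    out <- data.frame(BC = character(), CC = character(), DH = character(),
                      CO = character(), HA = character(), NC = integer(),
                      SN = integer())
    attr(out, "member_list") <- list()
    return(out)
  }
  key <- do.call(paste, c(records[.COND_FIELDS], sep = "\r"))
  ukey <- unique(key)              # first-appearance order
  sn <- match(key, ukey)
  first <- match(ukey, key)
  out <- records[first, .COND_FIELDS]
  out$NC <- as.integer(table(factor(sn, levels = seq_along(ukey))))
  out$SN <- seq_along(ukey)
  rownames(out) <- NULL
  attr(out, "member_list") <-
    stats::setNames(split(records$dataset_id, sn), out$SN)
  out
}

#' Look up a conditions group by key or serial number
#'
#' @param groups A \code{\link{group_by_conditions}} table.
#' @param key Character vector of length 5: (BC, CC, DH, CO, HA).
#' @param sn Group serial number.  Give exactly one of \code{key}/\code{sn}.
#' @return The matching one-row group (with its \code{members} attached as
#'   an attribute).
#' @export
select_group <- function(groups, key = NULL, sn = NULL) {
  if (is.null(key) == is.null(sn))
    stop("give exactly one of 'key' or 'sn'")
  if (!is.null(key)) {
    if (length(key) != 5)
      stop("key must have 5 elements: BC, CC, DH, CO, HA")
    hit <- which(groups$BC == key[[1]] & groups$CC == key[[2]] &
                 groups$DH == key[[3]] & groups$CO == key[[4]] &
                 groups$HA == key[[5]])
  } else {
    hit <- which(groups$SN == sn)
  }
  if (length(hit) != 1)
    stop("no such group; available serial numbers: ",
         paste(groups$SN, collapse = ", "))
  row <- groups[hit, ]
  attr(row, "members") <- attr(groups, "member_list")[[hit]]
  row
}

#' Write a conditions group table as TSV
#'
#' @param groups A \code{\link{group_by_conditions}} table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
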