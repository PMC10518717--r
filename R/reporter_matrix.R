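#' Reporter-intensity matrix with row and channel metadata
#'
#' The quantitative backbone of the package: a protein-group (or phosphosite)
#' by channel intensity matrix together with per-row evidence and filter flags
#' and per-channel design metadata. Intensities are raw (not log-transformed)
#' and nonnegative; missing values are `NA` (a MaxQuant reporter intensity of
#' zero is a non-detection and is read as missing).
#'
#' @param intensity numeric matrix, rows = proteins/sites, columns = channels.
#'   Values must be nonnegative or `NA`.
#' @param rows `data.frame` of row metadata. Recognised columns: `id`
#'   (unique identifiers; defaults to the matrix rownames), `gene`,
#'   `unique_peptides`, `msms`, and the logical flags `contaminant`,
#'   `reverse`, `only_by_site`. Missing columns are filled with defaults.
#' @param channels `data.frame` of channel metadata with one row per matrix
#'   column. Recognised columns: `label` (defaults to column names),
#'   `condition`, `plex`, `bridge` (logical), `role`.
#'
#' @return An object of class `reporter_matrix`: a list with elements
#'   `intensity`, `rows`, `channels`.
#' @export
#' @examples
#' m <- matrix(abs(rnorm(20, 1e6, 1e5)), 5, 4)
#' rm <- reporter_matrix(m, channels = data.frame(
#'   label = paste0("ch", 1:4), condition = rep(c("A", "B"), each = 2)))
#' dim(rm)
reporter_matrix <- function(intensity, rows = NULL, channels = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("P", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("ch", seq_len(ncol(intensity)))
  if (any(intensity[is.finite(intensity)] < 0))
    .stopf("intensities must be nonnegative or missing")

  rows <- .complete_row_meta(rows, rownames(intensity))
  channels <- .complete_channel_meta(channels, colnames(intensity))
  if (nrow(channels) != ncol(intensity))
    .stopf("channel metadata must describe every intensity column exactly once")
  if (anyDuplicated(rows$id))
    .stopf("row ids must be unique")
  if (anyDuplicated(channels$label))
    .stopf("channel labels must be unique")
  rownames(intensity) <- rows$id
  colnames(intensity) <- channels$label

  structure(list(intensity = intensity, rows = rows, channels = channels),
            class = "reporter_matrix")
}

.complete_row_meta <- function(rows, ids) {
  if (is.null(rows)) rows <- data.frame(id = ids, stringsAsFactors = FALSE)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(rows$id)) rows$id <- ids
  defaults <- list(gene = NA_character_, unique_peptides = NA_integer_,
                   msms = NA_integer_, contaminant = FALSE, reverse = FALSE,
                   only_by_site = FALSE)
  for (nm in names(defaults)) if (is.null(rows[[nm]])) rows[[nm]] <- defaults[[nm]]
  rownames(rows) <- NULL
  rows
}

.complete_channel_meta <- function(channels, labels) {
  if (is.null(channels)) channels <- data.frame(label = labels, stringsAsFactors = FALSE)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (is.null(channels$label)) channels$label <- labels
  defaults <- list(condition = NA_character_, plex = 1L, bridge = FALSE,
                   role = "sample")
  for (nm in names(defaults)) if (is.null(channels[[nm]])) channels[[nm]] <- defaults[[nm]]
  rownames(channels) <- NULL
  channels
}

#' @export
dim.reporter_matrix <- function(x) dim(x$intensity)

#' @export
print.reporter_matrix <- function(x, ...) {
  cat(sprintf("reporter_matrix: %d rows x %d channels\n",
              nrow(x$intensity), ncol(x$intensity)))
  conds <- unique(x$channels$condition)
  cat(sprintf("  plexes: %s; conditions: %s\n",
              paste(unique(x$channels$plex), collapse = ", "),
              paste(conds[!is.na(conds)], collapse = ", ")))
  cat(sprintf("  missing values: %d (%.1f%%)\n", sum(!is.finite(x$intensity)),
              100 * mean(!is.finite(x$intensity))))
  invisible(x)
}

#' @export
`[.reporter_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensity))
  if (missing(j)) j <- seq_len(ncol(x$intensity))
  reporter_matrix(x$intensity[i, j, drop = FALSE],
                  rows = x$rows[i, , drop = FALSE],
                  channels = x$channels[j, , drop = FALSE])
}

#' @export
as.matrix.reporter_matrix <- function(x, ...) x$intensity

#' Accessors for reporter_matrix components
#'
#' @param x a [reporter_matrix].
#' @return `intensities()` the numeric matrix; `channel_meta()` /
#'   `row_meta()` the respective metadata data frames.
#' @export
intensities <- function(x) {
  stopifnot(inherits(x, "reporter_matrix"))
  x$intensity
}

#' @rdname intensities
#' @export
channel_meta <- function(x) {
  stopifnot(inherits(x, "reporter_matrix"))
  x$channels
}

#' @rdname intensities
#' @export
row_meta <- function(x) {
  stopifnot(inherits(x, "reporter_matrix"))
  x$rows
}

#' Write a reporter matrix as a MaxQuant-style tab-separated table
#'
#' Produces a proteinGroups-like TSV: id/annotation columns, evidence counts,
#' `+`-coded flag columns and one `Reporter intensity corrected <k>` column
#' per channel (missing values written as 0, the MaxQuant convention). A
#' matrix written this way can be re-read with [read_protein_groups()].
#'
#' @param x a [reporter_matrix].
#' @param path output file path.
#' @return Invisibly, the channel map (`data.frame`) describing the written
#'   intensity columns, suitable for re-reading.
#' @export
write_reporter_matrix <- function(x, path) {
  stopifnot(inherits(x, "reporter_matrix"))
  flags <- function(l) ifelse(isTRUE_vec(l), "+", "")
  tab <- data.frame(
    `Majority protein IDs` = x$rows$id,
    `Gene names` = x$rows$gene,
    `Unique peptides` = x$rows$unique_peptides,
    `MS/MS count` = x$rows$msms,
    `Potential contaminant` = flags(x$rows$contaminant),
    `Reverse` = flags(x$rows$reverse),
    `Only identified by site` = flags(x$rows$only_by_site),
    check.names = FALSE, stringsAsFactors = FALSE)
  ints <- x$intensity
  ints[!is.finite(ints)] <- 0
  cols <- sprintf("Reporter intensity corrected %d", seq_len(ncol(ints)))
  for (k in seq_along(cols)) tab[[cols[k]]] <- ints[, k]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(data.frame(column = cols, label = x$channels$label,
                       condition = x$channels$condition, plex = x$channels$plex,
                       bridge = x$channels$bridge, role = x$channels$role,
                       stringsAsFactors = FALSE))
}

isTRUE_vec <- function(l) !is.na(l) & as.logical(l)
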