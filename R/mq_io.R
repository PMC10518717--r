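#' Default MaxQuant column-name dialect
#'
#' Column-name candidates for the fields the readers need, covering the
#' header spellings of MaxQuant 1.6 and 2.x. Pass a modified copy to the
#' readers to support other dialects.
#'
#' @return Named list of character vectors of candidate column names.
#' @export
mq_dialect <- function() {
  list(
    id              = c("Majority protein IDs", "Protein IDs", "Protein", "id"),
    gene            = c("Gene names", "Gene Names"),
    unique_peptides = c("Unique peptides", "Unique Peptides"),
    msms            = c("MS/MS count", "MS/MS Count", "MS/MS counts"),
    contaminant     = c("Potential contaminant", "Contaminant"),
    reverse         = c("Reverse"),
    only_by_site    = c("Only identified by site"),
    position        = c("Position", "Positions within proteins"),
    amino_acid      = c("Amino acid"),
    multiplicity    = c("Multiplicity")
  )
}

#' Read a channel map from a data frame, CSV/TSV or YAML file
#'
#' A channel map binds intensity column names of a MaxQuant table to channel
#' metadata. Required column: `column` (the intensity column header) and
#' `label`; optional: `condition`, `plex`, `bridge`, `role`.
#'
#' @param x a `data.frame`, or a path to a `.csv`/`.tsv` or `.yml`/`.yaml`
#'   file containing the map.
#' @return A normalized channel-map `data.frame`.
#' @export
read_channel_map <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      recs <- yaml::read_yaml(x)
      x <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      sep <- if (grepl("\\.tsv$", x, ignore.case = TRUE)) "\t" else ","
      x <- read.delim(x, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$column) || is.null(x$label))
    .stopf("channel map needs 'column' and 'label' columns")
  if (is.null(x$condition)) x$condition <- NA_character_
  if (is.null(x$plex)) x$plex <- 1L
  if (is.null(x$bridge)) x$bridge <- FALSE
  if (is.null(x$role)) x$role <- "sample"
  x$bridge <- isTRUE_vec(x$bridge)
  x
}

.pick_col <- function(tab, candidates) {
  hit <- candidates[candidates %in% names(tab)]
  if (length(hit)) hit[[1L]] else NULL
}

.flag_col <- function(tab, candidates) {
  cl <- .pick_col(tab, candidates)
  if (is.null(cl)) rep(FALSE, nrow(tab)) else !is.na(tab[[cl]]) & tab[[cl]] == "+"
}

.int_col <- function(tab, candidates) {
  cl <- .pick_col(tab, candidates)
  if (is.null(cl)) rep(NA_integer_, nrow(tab)) else suppressWarnings(as.integer(tab[[cl]]))
}

.read_mq_table <- function(source) {
  tab <- tryCatch(
    read.delim(source, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) .stopf("cannot read table '%s': %s", source, conditionMessage(e)))
  if (nrow(tab) == 0L || ncol(tab) == 0L) .stopf("table '%s' is empty", source)
  tab
}

.bind_intensity <- function(tab, channel_map, source) {
  missing_cols <- setdiff(channel_map$column, names(tab))
  if (length(missing_cols) == length(channel_map$column))
    .stopf("no intensity columns found; none of the mapped columns are present in '%s'", source)
  if (length(missing_cols))
    .stopf("intensity column(s) not found in '%s': %s", source,
           paste(missing_cols, collapse = ", "))
  ints <- as.matrix(tab[, channel_map$column, drop = FALSE])
  storage.mode(ints) <- "double"
  ints[!is.finite(ints) | ints == 0] <- NA_real_  # zero reporter = non-detection
  colnames(ints) <- channel_map$label
  ints
}

#' Read a MaxQuant proteinGroups-style table
#'
#' Parses a tab-separated protein-group table, binds the intensity columns
#' named in `channel_map` (e.g. `Reporter intensity corrected 1..10` or
#' `LFQ intensity <sample>`) to channel metadata, and collects evidence
#' counts and the `+`-coded contaminant / reverse / only-identified-by-site
#' flags. Zero reporter intensities are non-detections and become `NA`.
#' Protein-group ids with semicolon-separated accessions keep the leading
#' accession as the primary id.
#'
#' @param source path to a tab-separated file (or a connection).
#' @param channel_map see [read_channel_map()].
#' @param dialect column-name dialect, see [mq_dialect()].
#' @return A [reporter_matrix].
#' @export
read_protein_groups <- function(source, channel_map, dialect = mq_dialect()) {
  tab <- .read_mq_table(source)
  channel_map <- read_channel_map(channel_map)
  idcol <- .pick_col(tab, dialect$id)
  if (is.null(idcol))
    .stopf("no protein id column found (looked for: %s)",
           paste(dialect$id, collapse = ", "))
  ints <- .bind_intensity(tab, channel_map, source)
  ids <- sub(";.*$", "", as.character(tab[[idcol]]))
  ids <- make.unique(ids, sep = "#")
  genecol <- .pick_col(tab, dialect$gene)
  rows <- data.frame(
    id = ids,
    gene = if (is.null(genecol)) NA_character_ else as.character(tab[[genecol]]),
    unique_peptides = .int_col(tab, dialect$unique_peptides),
    msms = .int_col(tab, dialect$msms),
    contaminant = .flag_col(tab, dialect$contaminant),
    reverse = .flag_col(tab, dialect$reverse),
    only_by_site = .flag_col(tab, dialect$only_by_site),
    stringsAsFactors = FALSE)
  reporter_matrix(ints, rows = rows,
                  channels = channel_map[, c("label", "condition", "plex", "bridge", "role")])
}

#' Read a MaxQuant Phospho (STY)Sites-style table
#'
#' As [read_protein_groups()], but rows are phosphosites. Site ids are built
#' as `<protein>_<aa><position>___<multiplicity>`. Both collapsed tables (one
#' row per site, with or without a `Multiplicity` column) and
#' multiplicity-expanded tables (intensity columns suffixed `___1/2/3`, given
#' a channel map listing those expanded column names) are supported.
#'
#' @inheritParams read_protein_groups
#' @return A [reporter_matrix] with one row per site (and multiplicity state).
#' @export
read_phospho_sites <- function(source, channel_map, dialect = mq_dialect()) {
  tab <- .read_mq_table(source)
  channel_map <- read_channel_map(channel_map)
  idcol <- .pick_col(tab, dialect$id)
  protcol <- .pick_col(tab, c("Protein", "Proteins", "Leading proteins"))
  if (is.null(idcol) && is.null(protcol))
    .stopf("no site/protein id column found in '%s'", source)
  ints <- .bind_intensity(tab, channel_map, source)
  poscol <- .pick_col(tab, dialect$position)
  aacol <- .pick_col(tab, dialect$amino_acid)
  multcol <- .pick_col(tab, dialect$multiplicity)
  if (!is.null(protcol) && !is.null(poscol)) {
    prot <- sub(";.*$", "", as.character(tab[[protcol]]))
    aa <- if (is.null(aacol)) "" else as.character(tab[[aacol]])
    mult <- if (is.null(multcol)) 1L else suppressWarnings(as.integer(tab[[multcol]]))
    ids <- sprintf("%s_%s%s___%d", prot, aa, as.character(tab[[poscol]]), mult)
  } else {
    ids <- as.character(tab[[idcol]])
  }
  ids <- make.unique(ids, sep = "#")
  genecol <- .pick_col(tab, dialect$gene)
  rows <- data.frame(
    id = ids,
    gene = if (is.null(genecol)) NA_character_ else as.character(tab[[genecol]]),
    unique_peptides = .int_col(tab, dialect$unique_peptides),
    msms = .int_col(tab, dialect$msms),
    contaminant = .flag_col(tab, dialect$contaminant),
    reverse = .flag_col(tab, dialect$reverse),
    only_by_site = .flag_col(tab, dialect$only_by_site),
    stringsAsFactors = FALSE)
  reporter_matrix(ints, rows = rows,
                  channels = channel_map[, c("label", "condition", "plex", "bridge", "role")])
}

#' Row-filter rules for reporter matrices
#'
#' The standard proteomics row filters: decoy (reversed) sequences, known
#' contaminants, proteins only identified by modified peptides, a minimum
#' unique-peptide count (the SIP analysis drops entries with fewer than two
#' unique peptides), and a minimum number of valid (finite) values per
#' condition group (the profiling analysis requires valid values in at least
#' three replicates).
#'
#' @param drop_contaminants,drop_reverse,drop_only_by_site logical.
#' @param min_unique_peptides minimum unique-peptide count (0 disables).
#' @param min_valid_per_group minimum finite values required in *every*
#'   condition group (0 disables).
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(drop_contaminants = TRUE, drop_reverse = TRUE,
                         drop_only_by_site = TRUE, min_unique_peptides = 0L,
                         min_valid_per_group = 0L) {
  structure(list(
    drop_contaminants = isTRUE(drop_contaminants),
    drop_reverse = isTRUE(drop_reverse),
    drop_only_by_site = isTRUE(drop_only_by_site),
    min_unique_peptides = .check_count(min_unique_peptides, "min_unique_peptides"),
    min_valid_per_group = .check_count(min_valid_per_group, "min_valid_per_group")),
    class = "filter_rules")
}

#' Apply row filters to a reporter matrix
#'
#' Removes rows violating any enabled rule in `rules`; the per-rule removal
#' counts are attached as attribute `"filter_log"` and reported via
#' `message()`. Filtering is idempotent.
#'
#' @param x a [reporter_matrix].
#' @param rules a [filter_rules] object.
#' @param groups channel grouping for the valid-value rule: a character
#'   vector of length `ncol(x)`, a named list of channel labels per group,
#'   or `NULL` to use the channel `condition` metadata. Channels with `NA`
#'   group are ignored by the rule.
#' @return The filtered [reporter_matrix].
#' @export
filter_entries <- function(x, rules = filter_rules(), groups = NULL) {
  stopifnot(inherits(x, "reporter_matrix"), inherits(rules, "filter_rules"))
  n <- nrow(x$intensity)
  drop <- rep(FALSE, n)
  log <- list()
  mark <- function(bad, rule) {
    newly <- bad & !drop
    log[[rule]] <<- sum(newly)
    drop <<- drop | bad
  }
  if (rules$drop_contaminants) mark(isTRUE_vec(x$rows$contaminant), "contaminant")
  if (rules$drop_reverse) mark(isTRUE_vec(x$rows$reverse), "reverse")
  if (rules$drop_only_by_site) mark(isTRUE_vec(x$rows$only_by_site), "only_by_site")
  if (rules$min_unique_peptides > 0L) {
    up <- x$rows$unique_peptides
    mark(!is.na(up) & up < rules$min_unique_peptides, "min_unique_peptides")
  }
  if (rules$min_valid_per_group > 0L) {
    if (is.list(groups)) {
      unknown <- setdiff(unlist(groups), x$channels$label)
      if (length(unknown))
        .stopf("'groups' references unknown channels: %s", paste(unknown, collapse = ", "))
      g <- rep(NA_character_, ncol(x$intensity))
      for (nm in names(groups)) g[x$channels$label %in% groups[[nm]]] <- nm
    } else {
      g <- groups %||% x$channels$condition
      if (length(g) != ncol(x$intensity))
        .stopf("'groups' must name a group for each of the %d channels", ncol(x$intensity))
    }
    gs <- stats::na.omit(unique(g))
    if (length(gs) == 0L) .stopf("valid-value filter requested but no channel groups defined")
    valid <- vapply(gs, function(gr)
      rowSums(is.finite(x$intensity[, which(g == gr), drop = FALSE])), numeric(n))
    mark(apply(valid < rules$min_valid_per_group, 1L, any), "min_valid_per_group")
  }
  out <- x[!drop, ]
  flog <- data.frame(rule = names(log), removed = unlist(log, use.names = FALSE),
                     stringsAsFactors = FALSE)
  attr(out, "filter_log") <- flog
  if (nrow(flog) && sum(flog$removed) > 0)
    message(sprintf("filter_entries: removed %d rows (%s)", sum(flog$removed),
                    paste(sprintf("%s: %d", flog$rule, flog$removed), collapse = ", ")))
  out
}
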