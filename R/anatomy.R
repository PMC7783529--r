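#' Canonical tissue vocabulary
#'
#' The fixed tissue labels accepted by [load_anatomy()]. `"germline"` covers
#' the rachis plus non-somatic germ cells (a pseudo-record rather than
#' discrete cells, since germ nuclei open onto a shared cytoplasm);
#' `"cuticle"` is the extracellular secreted layer (zero nuclei). Free-text
#' tissues are rejected by default so a typo cannot silently split an
#' aggregate.
#'
#' @export
canonical_tissues <- c("intestine", "hypodermis", "cuticle",
                       "body wall muscle", "pharynx", "neurons",
                       "somatic gonad", "germline", "other")

#' Load an anatomy table (cell -> tissue, nuclei, ploidy)
#'
#' Schema: `cell,tissue,somatic,nuclei,ploidy_c`. `nuclei` is the number of
#' nuclei in the (possibly syncytial) cell — e.g. 139 for the hypodermal hyp7
#' syncytium, 6 for the pharyngeal muscle pm1; zero is permitted only for
#' non-cellular structures such as the cuticle. `ploidy_c` is the DNA content
#' per nucleus as a C-value (2 = diploid; 32 = young-adult intestine), and
#' must be >= 2 for nucleated cells. Lines starting with `#` are comments.
#'
#' @param path CSV file.
#' @param extra_tissues additional tissue labels to accept beyond
#'   [canonical_tissues].
#' @return A data.frame of validated records with columns `cell`, `tissue`,
#'   `somatic` (logical), `nuclei` (integer), `ploidy_c` (numeric).
#' @examples
#' tab <- load_anatomy(system.file("extdata", "celegans_anatomy.csv",
#'                                 package = "wormvolumes"))
#' genome_equivalents(tab[tab$cell == "hyp7", ])  # 139
#' @export
load_anatomy <- function(path, extra_tissues = character()) {
  if (!file.exists(path)) stop("anatomy table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell", "tissue", "somatic", "nuclei", "ploidy_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("anatomy schema error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  df$somatic <- as.logical(df$somatic)
  rowlab <- function(i) sprintf("anatomy schema error in '%s' at data row %d (cell '%s'): ",
                                path, i, df$cell[i])
  allowed <- c(canonical_tissues, extra_tissues)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$cell[i]) || !nzchar(df$cell[i]))
      stop(rowlab(i), "empty cell name")
    if (!df$tissue[i] %in% allowed)
      stop(rowlab(i), "unknown tissue '", df$tissue[i],
           "' (declare it via extra_tissues)")
    if (is.na(df$somatic[i]))
      stop(rowlab(i), "somatic must be TRUE/FALSE")
    if (is.na(df$nuclei[i]) || df$nuclei[i] < 0 || df$nuclei[i] != round(df$nuclei[i]))
      stop(rowlab(i), "nuclei must be a non-negative integer")
    if (df$nuclei[i] > 0 && (is.na(df$ploidy_c[i]) || df$ploidy_c[i] < 2))
      stop(rowlab(i), "ploidy_c must be >= 2 for a nucleated cell")
  }
  if (anyDuplicated(df$cell))
    stop("anatomy schema error in '", path, "': duplicate cell name(s) ",
         paste(unique(df$cell[duplicated(df$cell)]), collapse = ", "))
  df$nuclei <- as.integer(df$nuclei)
  df$ploidy_c <- as.double(df$ploidy_c)
  df
}

#' Diploid genome equivalents of a cell record
#'
#' `nuclei * ploidy_c / 2`: the number of diploid genome copies a cell
#' carries, the denominator used to normalise cell volume for syncytia
#' (many nuclei) and polyploid cells (C-value > 2). A mononucleate diploid
#' cell has exactly 1; hyp7 (139 diploid nuclei) has 139; a mononucleate 32C
#' intestinal cell has 16. Linear in both `nuclei` and `ploidy_c`.
#'
#' @param records an anatomy data.frame (rows of [load_anatomy()] output), or
#'   a numeric vector of nuclei counts if `ploidy_c` is given.
#' @param ploidy_c per-nucleus C-values, recycled; only used when `records`
#'   is a plain numeric vector.
#' @return Numeric vector of genome equivalents.
#' @export
genome_equivalents <- function(records, ploidy_c = NULL) {
  if (is.data.frame(records)) {
    records$nuclei * records$ploidy_c / 2
  } else {
    if (is.null(ploidy_c)) stop("ploidy_c required when records is not a data.frame")
    as.double(records) * as.double(ploidy_c) / 2
  }
}

#' Regroup rules: collection label -> tissue label, with per-cell overrides
#'
#' Encodes the relabelling applied before aggregation — chiefly separating
#' the extracellular cuticle from the hypodermis collection that contains it,
#' and the rachis/germ cells from the somatic gonad. Rules must be total over
#' the collections present (map every collection, possibly to itself).
#'
#' @param collections named character vector: `source collection -> tissue`.
#' @param cells optional named character vector of per-cell overrides:
#'   `cell name -> tissue`.
#' @return An object of class `regroup_rules`.
#' @seealso [regroup()], [identity_rules()]
#' @export
regroup_rules <- function(collections, cells = character()) {
  collections <- vapply(collections, as.character, "")
  if (is.null(names(collections)) || any(!nzchar(names(collections))))
    stop("collections must be a fully named character vector")
  structure(list(collections = collections, cells = cells),
            class = "regroup_rules")
}

#' @rdname regroup_rules
#' @param labels collection labels to map to themselves.
#' @export
identity_rules <- function(labels) {
  labels <- unique(as.character(labels))
  regroup_rules(stats::setNames(labels, labels))
}

#' Load regroup rules from a JSON file
#'
#' Expected shape: `{"collections": {"src": "tissue", ...},
#' "cells": {"cell": "tissue", ...}}` (the `cells` member is optional).
#'
#' @param path JSON file.
#' @return A [regroup_rules()] object.
#' @export
load_regroup_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regroup_rules(unlist(x$collections),
                if (is.null(x$cells)) character() else unlist(x$cells))
}

#' Rewrite tissue labels on a measurement table
#'
#' Only labels change; every volume is untouched, so the total volume is
#' conserved exactly. Errors if any measurement's collection is not covered
#' by the rules.
#'
#' @param measurements a [measure_cells()] data.frame.
#' @param rules a [regroup_rules()] object.
#' @return The measurement table with `tissue` rewritten.
#' @export
regroup <- function(measurements, rules) {
  stopifnot(inherits(rules, "regroup_rules"))
  uncovered <- setdiff(unique(measurements$tissue), names(rules$collections))
  if (length(uncovered))
    stop("regroup rules do not cover collection(s): ",
         paste(uncovered, collapse = ", "))
  new <- unname(rules$collections[measurements$tissue])
  if (length(rules$cells)) {
    hit <- measurements$cell %in% names(rules$cells)
    new[hit] <- unname(rules$cells[measurements$cell[hit]])
  }
  measurements$tissue <- new
  measurements
}
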