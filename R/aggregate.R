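#' Summarise calibrated cell volumes by tissue
#'
#' Joins measurements to anatomy records (strict: every measured cell must
#' have a record) and aggregates per tissue: total volume, nuclei, diploid
#' genome equivalents, mean cell volume and mean volume per diploid genome.
#' Fractions (`volume_fraction`, `nuclei_fraction`, `genome_fraction`) are
#' normalised over the tissues that remain after `exclude` is removed — the
#' convention used for composition analyses, where the extracellular cuticle
#' is dropped before computing "relative contribution to the final volume".
#' `include_germline` toggles the non-somatic germline/rachis pseudo-record
#' in or out (composition with vs. without germ cells).
#'
#' @param measurements a [measure_cells()] data.frame (rows with
#'   `excluded = TRUE` are dropped with a message).
#' @param records an anatomy data.frame from [load_anatomy()].
#' @param include_germline include non-somatic records (germline/rachis)?
#' @param exclude tissue labels removed from the analysis before fractions
#'   are computed (e.g. `"cuticle"`).
#' @return A data.frame, one row per tissue, sorted by descending
#'   `total_volume`: `tissue`, `n_cells`, `total_volume`, `volume_fraction`,
#'   `nuclei_total`, `nuclei_fraction`, `genome_equivalents_total`,
#'   `genome_fraction`, `mean_cell_volume`, `mean_volume_per_genome`.
#' @export
summarize_tissues <- function(measurements, records, include_germline = TRUE,
                              exclude = character()) {
  m <- measurements[!measurements$excluded, , drop = FALSE]
  if (nrow(m) < nrow(measurements))
    message(nrow(measurements) - nrow(m), " excluded measurement(s) dropped from aggregation")
  orphans <- setdiff(m$cell, records$cell)
  if (length(orphans))
    stop("measured cell(s) without anatomy record: ",
         paste(orphans, collapse = ", "))
  j <- merge(m, records, by = "cell", suffixes = c("", ".anatomy"))
  # tissue label comes from the measurement side (post-regroup); the anatomy
  # side supplies nuclei/ploidy/somatic
  if (!include_germline) j <- j[j$somatic, , drop = FALSE]
  j <- j[!j$tissue %in% exclude, , drop = FALSE]
  if (!nrow(j)) stop("no cells left to summarise after exclusions")
  j$ge <- genome_equivalents(j$nuclei, j$ploidy_c)
  j$vpg <- ifelse(j$ge > 0, j$calibrated_volume_um3 / j$ge, NA_real_)

  split_t <- split(j, j$tissue)
  out <- do.call(rbind, lapply(split_t, function(d) {
    data.frame(tissue = d$tissue[1L],
               n_cells = nrow(d),
               total_volume = sum(d$calibrated_volume_um3),
               nuclei_total = sum(d$nuclei),
               genome_equivalents_total = sum(d$ge),
               mean_cell_volume = mean(d$calibrated_volume_um3),
               mean_volume_per_genome = if (any(!is.na(d$vpg)))
                 mean(d$vpg, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$volume_fraction <- out$total_volume / sum(out$total_volume)
  out$nuclei_fraction <- out$nuclei_total / sum(out$nuclei_total)
  out$genome_fraction <- out$genome_equivalents_total / sum(out$genome_equivalents_total)
  out <- out[order(-out$total_volume, out$tissue, method = "radix"), ]
  rownames(out) <- NULL
  out[, c("tissue", "n_cells", "total_volume", "volume_fraction",
          "nuclei_total", "nuclei_fraction", "genome_equivalents_total",
          "genome_fraction", "mean_cell_volume", "mean_volume_per_genome")]
}

#' Merge somatic gonad and germline into a single "gonads" row
#'
#' Reporting convention: when the germline is included, the gonad is shown as
#' one tissue comprising the somatic sheath/spermatheca/uterus plus the
#' rachis and germ cells it contains. Totals are summed and fractions
#' recomputed; means are volume-weighted accordingly.
#'
#' @param summaries a [summarize_tissues()] data.frame.
#' @return The table with `somatic gonad` and `germline` replaced by
#'   `gonads` (when both or either are present), re-sorted.
#' @export
merge_gonads <- function(summaries) {
  sel <- summaries$tissue %in% c("somatic gonad", "germline")
  if (!any(sel)) return(summaries)
  g <- summaries[sel, , drop = FALSE]
  merged <- data.frame(tissue = "gonads",
                       n_cells = sum(g$n_cells),
                       total_volume = sum(g$total_volume),
                       volume_fraction = sum(g$volume_fraction),
                       nuclei_total = sum(g$nuclei_total),
                       nuclei_fraction = sum(g$nuclei_fraction),
                       genome_equivalents_total = sum(g$genome_equivalents_total),
                       genome_fraction = sum(g$genome_fraction),
                       mean_cell_volume = sum(g$total_volume) / sum(g$n_cells),
                       mean_volume_per_genome = sum(g$total_volume) /
                         sum(g$genome_equivalents_total),
                       stringsAsFactors = FALSE)
  out <- rbind(summaries[!sel, , drop = FALSE], merged)
  out <- out[order(-out$total_volume, out$tissue, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Volume per diploid genome for measured cells
#'
#' `calibrated_volume / genome_equivalents` — the normalisation that puts
#' syncytia (many nuclei) and polyploid cells (C > 2) on a common per-genome
#' scale. Undefined (NA) where genome equivalents are zero (e.g. the
#' extracellular cuticle); such cells are excluded from per-genome analyses.
#'
#' @param measurements a [measure_cells()] data.frame.
#' @param records an anatomy data.frame.
#' @return A data.frame `cell`, `tissue`, `calibrated_volume_um3`,
#'   `genome_equivalents`, `volume_per_genome` for non-excluded cells.
#' @export
volume_per_genome <- function(measurements, records) {
  m <- measurements[!measurements$excluded, , drop = FALSE]
  orphans <- setdiff(m$cell, records$cell)
  if (length(orphans))
    stop("measured cell(s) without anatomy record: ",
         paste(orphans, collapse = ", "))
  j <- merge(m, records, by = "cell", suffixes = c("", ".anatomy"))
  ge <- genome_equivalents(j$nuclei, j$ploidy_c)
  data.frame(cell = j$cell, tissue = j$tissue,
             calibrated_volume_um3 = j$calibrated_volume_um3,
             genome_equivalents = ge,
             volume_per_genome = ifelse(ge > 0, j$calibrated_volume_um3 / ge,
                                        NA_real_),
             stringsAsFactors = FALSE)
}

#' Fractions of cells below size thresholds
#'
#' For each threshold, the fraction of values strictly below it (`value <
#' threshold`). Strict inequality matches the reporting convention for
#' statements like "for 86% of cells the volume per diploid genome was below
#' 1,000 µm³"; the non-strict variant is returned alongside so the two can
#' be compared when they differ on real data. Raw fractions are retained;
#' rounding to percentages happens only at report time.
#'
#' @param values non-negative volumes (µm³); germline/rachis pseudo-cells are
#'   expected to be excluded upstream.
#' @param thresholds µm³ cutoffs; default `c(200, 1000)`.
#' @return An object of class `distribution_stats`: list with `thresholds`,
#'   `fractions_below` (strict), `fractions_at_or_below` (non-strict), `n`,
#'   and the retained `values` for plotting.
#' @export
distribution_stats <- function(values, thresholds = c(200, 1000)) {
  values <- as.double(values)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  if (any(values < 0)) stop("volumes must be non-negative")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  thresholds <- sort(thresholds)
  structure(list(
    thresholds = thresholds,
    fractions_below = vapply(thresholds, function(t) mean(values < t), 0),
    fractions_at_or_below = vapply(thresholds, function(t) mean(values <= t), 0),
    n = length(values),
    values = values
  ), class = "distribution_stats")
}

#' @export
print.distribution_stats <- function(x, ...) {
  cat(sprintf("<distribution over %d cells>\n", x$n))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  < %g um^3: %d%%  (<=: %d%%)\n", x$thresholds[i],
                round(100 * x$fractions_below[i]),
                round(100 * x$fractions_at_or_below[i])))
  invisible(x)
}

#' Rank tissues by total volume
#'
#' Strict descending order by `total_volume`; ties broken lexicographically
#' and flagged via the `tied` column / `"ties"` attribute.
#'
#' @param summaries a [summarize_tissues()] data.frame.
#' @return The summary rows reordered, with a logical `tied` column;
#'   `attr(, "ties")` is `TRUE` if any tie occurred.
#' @export
rank_tissues <- function(summaries) {
  if (!nrow(summaries)) stop("no tissue summaries to rank")
  out <- summaries[order(-summaries$total_volume, summaries$tissue,
                         method = "radix"), , drop = FALSE]
  out$tied <- duplicated(out$total_volume) |
    duplicated(out$total_volume, fromLast = TRUE)
  rownames(out) <- NULL
  attr(out, "ties") <- any(out$tied)
  out
}

#' Extreme-cell and per-genome tissue ratios
#'
#' Two headline comparisons: (1) the ratio of the largest cell's volume to
#' the second largest (e.g. the hyp7 syncytium vs the largest intestinal
#' cell); (2) for each tissue, the mean volume per diploid genome of its
#' cells divided by the mean over all cells outside that tissue (e.g. body
#' wall muscle carrying several-fold more volume per genome copy than the
#' rest). Cells with zero genome equivalents are excluded from (2).
#'
#' @param measurements a [measure_cells()] data.frame (>= 2 cells).
#' @param records an anatomy data.frame.
#' @return A list: `largest_cells` (names of top two), `top_ratio`,
#'   `per_genome_ratio` (named vector by tissue).
#' @export
extreme_ratios <- function(measurements, records) {
  m <- measurements[!measurements$excluded, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 measured cells")
  ord <- order(-m$calibrated_volume_um3, m$cell, method = "radix")
  top <- m[ord[1:2], ]
  vpg <- volume_per_genome(m, records)
  vpg <- vpg[!is.na(vpg$volume_per_genome), , drop = FALSE]
  tissues <- sort(unique(vpg$tissue))
  ratio <- vapply(tissues, function(t) {
    inside <- vpg$volume_per_genome[vpg$tissue == t]
    outside <- vpg$volume_per_genome[vpg$tissue != t]
    if (!length(outside)) return(NA_real_)
    mean(inside) / mean(outside)
  }, 0)
  list(largest_cells = top$cell,
       top_ratio = top$calibrated_volume_um3[1L] / top$calibrated_volume_um3[2L],
       per_genome_ratio = ratio)
}

#' Bar plot of tissue volume fractions
#'
#' Simple base-graphics companion to [summarize_tissues()].
#'
#' @param summaries a [summarize_tissues()] data.frame.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_tissue_fractions <- function(summaries, ...) {
  graphics::barplot(stats::setNames(100 * summaries$volume_fraction,
                                    summaries$tissue),
                    ylab = "volume fraction (%)", las = 2, ...)
}
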