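# Contaminant filtering: fragments present in blank injections (SPME fiber
# polysiloxanes, lab air) are removed before compound reconstruction.

detection_floor <- function(table, noise = NULL) {
  if (!is.null(noise)) return(noise$peak_threshold_factor * noise$baseline_sd)
  # without a noise model, any observed (non-missing) value counts as
  # detected: aligned tables encode sub-floor signals as missing already
  0
}

new_contaminant_report <- function(table, flagged_ids, reason) {
  frag <- table$fragments
  flagged <- frag[frag$fragment_id %in% flagged_ids,
                  c("fragment_id", "mz", "rt_s"), drop = FALSE]
  flagged$reason <- if (nrow(flagged)) reason else character(0)
  structure(list(flagged = flagged,
                 n_in = nrow(frag), n_flagged = nrow(flagged),
                 n_out = nrow(frag) - nrow(flagged)),
            class = "contaminant_report")
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf("contaminant_report: %d / %d fragments flagged (%s)\n",
              x$n_flagged, x$n_in,
              paste(unique(x$flagged$reason), collapse = ", ")))
  invisible(x)
}

blank_stats <- function(table, floor) {
  blanks <- role_columns(table, "blank")
  bio <- role_columns(table, "biological")
  bm <- table$matrix[, blanks, drop = FALSE]
  detected <- !is.na(bm) & bm > floor
  list(
    blank_ids = blanks,
    frac_detected = rowMeans(detected),
    blank_mean = rowMeans(ifelse(detected, bm, NA), na.rm = TRUE),
    bio_median = apply(table$matrix[, bio, drop = FALSE], 1, median,
                       na.rm = TRUE))
}

#' Flag SPME-fiber polysiloxane fragments
#'
#' Flags fragments whose m/z lies on the polysiloxane ion series *and* that
#' are detected in blank injections. The blank evidence is required because
#' m/z alone is not diagnostic: genuine analytes also produce ions at m/z 73
#' and other siloxane masses.
#'
#' @param table a [fragment_table()] with at least one blank sample
#' @param mz_list integer m/z values of the siloxane series
#' @param floor detection floor; observed values at or below it do not count
#'   as detected
#' @return a `contaminant_report` (`flagged` data.frame with reason
#'   `"polysiloxane_mz"`, plus in/flagged/out counts)
#' @export
flag_polysiloxane <- function(table, mz_list = POLYSILOXANE_MZ, floor = 0) {
  if (!length(mz_list))
    stop_vocnet("mz_list must be non-empty", "vocnet_bad_config")
  if (!length(role_columns(table, "blank")))
    stop_vocnet("no blank samples in table", "vocnet_no_blanks")
  bs <- blank_stats(table, floor)
  hit <- table$fragments$mz %in% as.integer(mz_list) &
    is.finite(bs$blank_mean) & bs$blank_mean > floor
  new_contaminant_report(table, table$fragments$fragment_id[hit],
                         "polysiloxane_mz")
}

#' Flag blank-present contaminant fragments
#'
#' A fragment is flagged when it is detected in at least `blank_fraction` of
#' the blank injections and its mean blank intensity reaches
#' `intensity_fraction` of its median intensity over biological samples.
#' The second condition keeps genuine analytes that bleed trivially into
#' blanks (carry-over) from being discarded.
#'
#' @inheritParams flag_polysiloxane
#' @param blank_fraction minimum fraction of blanks in which the fragment is
#'   detected
#' @param intensity_fraction minimum blank-mean / biological-median intensity
#'   ratio
#' @return a `contaminant_report` with reason `"blank_present"`
#' @export
flag_blank_present <- function(table, blank_fraction = 0.5,
                               intensity_fraction = 0.1, floor = 0) {
  if (!length(role_columns(table, "blank")))
    stop_vocnet("no blank samples in table", "vocnet_no_blanks")
  bs <- blank_stats(table, floor)
  rel <- bs$blank_mean / bs$bio_median
  hit <- bs$frac_detected >= blank_fraction &
    is.finite(bs$blank_mean) &
    (is.na(bs$bio_median) | !is.finite(rel) | rel >= intensity_fraction)
  hit[is.na(hit)] <- FALSE
  new_contaminant_report(table, table$fragments$fragment_id[hit],
                         "blank_present")
}

#' Drop flagged fragments from a table
#'
#' Removes the union of fragments flagged in one or more contaminant
#' reports; the sample set is unchanged. Idempotent.
#'
#' @param table a [fragment_table()]
#' @param reports a single `contaminant_report` or a list of them
#' @return the filtered [fragment_table()]
#' @export
drop_flagged <- function(table, reports) {
  if (inherits(reports, "contaminant_report")) reports <- list(reports)
  flagged <- unique(unlist(lapply(reports, function(r) r$flagged$fragment_id)))
  keep <- !(table$fragments$fragment_id %in% flagged)
  out <- table
  out$fragments <- table$fragments[keep, , drop = FALSE]
  rownames(out$fragments) <- NULL
  out$matrix <- table$matrix[keep, , drop = FALSE]
  out
}

#' Write a contaminant report to CSV
#'
#' @param report a `contaminant_report` (or list of reports, concatenated)
#' @param path output CSV (`fragment_id`, `mz`, `rt_s`, `reason`)
#' @export
write_contaminant_report <- function(report, path) {
  if (inherits(report, "contaminant_report")) report <- list(report)
  flagged <- do.call(rbind, lapply(report, function(r) r$flagged))
  write.csv(flagged, path, row.names = FALSE)
  invisible(path)
}
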