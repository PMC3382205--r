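# Pseudo-spectrum assembly, quantification-ion selection and spectral
# library matching for candidate compounds.

#' Assemble a pseudo-spectrum for one cluster
#'
#' Each member fragment contributes its median intensity across the samples
#' in which it was detected (biological + reference); the peak list is then
#' jointly rescaled so the base peak is 999. Using the per-sample median is
#' robust to single-chromatogram saturation and replaces any manual choice
#' of a "best" chromatogram. The spectrum's retention time is the median
#' member RT.
#'
#' @param cluster_ids character vector of member fragment ids
#' @param table the [fragment_table()]
#' @param candidate_id id carried into downstream results
#' @return object of class `pseudo_spectrum`: `candidate_id`, `rt_s`,
#'   `peaks` (named by m/z, base 999), `members`, and `mz_fragments`
#'   (fragment id backing each m/z peak)
#' @export
assemble_spectrum <- function(cluster_ids, table, candidate_id = "C001") {
  if (!length(cluster_ids))
    stop_vocnet("cannot assemble a spectrum from an empty cluster",
                "vocnet_empty_cluster")
  cols <- role_columns(table, c("biological", "reference"))
  idx <- match(cluster_ids, table$fragments$fragment_id)
  med <- apply(table$matrix[idx, cols, drop = FALSE], 1, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  mz <- table$fragments$mz[idx]
  # merge fragments sharing an m/z bin: keep the stronger one per bin
  keep <- order(med, decreasing = TRUE)
  keep <- keep[!duplicated(mz[keep])]
  keep <- keep[order(mz[keep])]
  peaks <- med[keep]
  if (max(peaks) <= 0)
    stop_vocnet("cluster has no detected intensities", "vocnet_empty_cluster")
  peaks <- setNames(peaks / max(peaks) * 999, mz[keep])
  structure(list(candidate_id = candidate_id,
                 rt_s = median(table$fragments$rt_s[idx]),
                 peaks = peaks,
                 members = cluster_ids,
                 mz_fragments = setNames(cluster_ids[keep], mz[keep])),
            class = "pseudo_spectrum")
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("pseudo_spectrum %s @ %.1f s: %d peaks (base m/z %s)\n",
              x$candidate_id, x$rt_s, length(x$peaks),
              names(x$peaks)[which.max(x$peaks)]))
  invisible(x)
}

#' Assemble pseudo-spectra for all clusters
#'
#' @param clusters a `fragment_clusters` object
#' @param table the [fragment_table()]
#' @return named list of `pseudo_spectrum`, one per cluster
#' @export
assemble_spectra <- function(clusters, table) {
  ids <- split(clusters$assignment$fragment_id,
               clusters$assignment$cluster_id)
  out <- lapply(names(ids), function(cl)
    assemble_spectrum(ids[[cl]], table, candidate_id = cl))
  setNames(out, names(ids))
}

#' Select the quantification ion for a candidate
#'
#' Returns the highest-intensity m/z of the spectrum that does not occur in
#' any co-eluting candidate's spectrum, so the chosen ion tracks this
#' compound alone. If every peak is shared, the base peak is returned with a
#' `shared_quant_ion` warning.
#'
#' @param spectrum a `pseudo_spectrum`
#' @param co_eluting list of `pseudo_spectrum` for other candidates eluting
#'   within the co-elution window of this one
#' @return integer m/z
#' @export
select_quant_ion <- function(spectrum, co_eluting = list()) {
  taken <- unique(unlist(lapply(co_eluting, function(s) names(s$peaks))))
  ord <- names(sort(spectrum$peaks, decreasing = TRUE))
  free <- ord[!(ord %in% taken)]
  if (length(free)) return(as.integer(free[1]))
  warning(sprintf("%s: every ion shared with a co-eluting candidate; using base peak",
                  spectrum$candidate_id),
          call. = FALSE)
  as.integer(ord[1])
}

sqrt_vec <- function(peaks, bins) {
  v <- setNames(numeric(length(bins)), bins)
  v[names(peaks)[names(peaks) %in% bins]] <-
    sqrt(peaks[names(peaks) %in% bins])
  v
}

#' Forward and reverse spectral match
#'
#' Cosine similarity on square-root-scaled intensities, scaled to the
#' conventional 0--1000 range. The forward match is computed over the union
#' of both peak lists; the reverse match restricts the comparison to the
#' query's m/z bins, ignoring library peaks the (typically fragment-poor)
#' pseudo-spectrum never had a chance to contain.
#'
#' @param query a `pseudo_spectrum` (or any object with a `peaks` vector
#'   named by m/z)
#' @param entry a `spectrum_entry`
#' @return named numeric: `forward`, `reverse` (each 0--1000)
#' @export
match_spectrum <- function(query, entry) {
  qp <- query$peaks
  ep <- entry$peaks
  if (!length(qp) || !length(ep))
    stop_vocnet("cannot match empty spectra", "vocnet_empty_spectrum")
  cosine1000 <- function(bins) {
    q <- sqrt_vec(qp, bins); e <- sqrt_vec(ep, bins)
    den <- sqrt(sum(q^2)) * sqrt(sum(e^2))
    if (den == 0) return(0)
    1000 * sum(q * e) / den
  }
  c(forward = cosine1000(union(names(qp), names(ep))),
    reverse = cosine1000(names(qp)))
}

#' Identify candidates against a spectral library
#'
#' For each pseudo-spectrum the best library entry by forward match is
#' selected (ties broken by higher reverse match, then by name). A candidate
#' is identified when its forward match exceeds `match_min` *and* every
#' member-fragment m/z of the cluster occurs in the entry's peak list (the
#' containment rule); otherwise it is labelled `Ni_01`, `Ni_02`, ... in
#' retention-time order among the unidentified candidates.
#'
#' @param spectra named list of `pseudo_spectrum` (see [assemble_spectra()])
#' @param library list of `spectrum_entry` from [read_msp()]
#' @param match_min forward-match threshold on the 0--1000 scale
#' @param co_elution_window_s window (seconds) within which other candidates
#'   count as co-eluting for quantification-ion selection
#' @return data.frame with one row per candidate: `candidate_id`, `name`,
#'   `cas`, `forward_match`, `reverse_match`, `identified`, `quant_mz`,
#'   `quant_fragment_id`, `rt_s`, `n_fragments`
#' @export
identify_compounds <- function(spectra, library, match_min = 800,
                               co_elution_window_s = 9) {
  if (!length(library))
    stop_vocnet("spectral library is empty", "vocnet_empty_library")
  rts <- vapply(spectra, function(s) s$rt_s, numeric(1))
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    scores <- vapply(library, function(e) match_spectrum(sp, e),
                     numeric(2))
    ord <- order(-scores["forward", ], -scores["reverse", ],
                 vapply(library, `[[`, character(1), "name"))
    best <- ord[1]
    entry <- library[[best]]
    contained <- all(names(sp$peaks) %in% names(entry$peaks))
    identified <- scores["forward", best] > match_min && contained
    neighbors <- spectra[abs(rts - sp$rt_s) <= co_elution_window_s &
                           seq_along(spectra) != i]
    quant_mz <- select_quant_ion(sp, neighbors)
    data.frame(
      candidate_id = sp$candidate_id,
      name = if (identified) entry$name else NA_character_,
      cas = if (identified) entry$cas else NA_character_,
      forward_match = round(scores["forward", best], 1),
      reverse_match = round(scores["reverse", best], 1),
      identified = identified,
      quant_mz = quant_mz,
      quant_fragment_id = unname(sp$mz_fragments[as.character(quant_mz)]),
      rt_s = sp$rt_s,
      n_fragments = length(sp$members),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # unidentified candidates are numbered Ni_01, Ni_02, ... in RT order
  un <- which(!out$identified)
  un <- un[order(out$rt_s[un], out$candidate_id[un])]
  out$name[un] <- sprintf("Ni_%02d", seq_along(un))
  rownames(out) <- NULL
  out
}

#' Write an identification table to CSV
#'
#' Columns mirror a per-compound summary table: candidate, assigned name,
#' retention time, quantification ion, forward/reverse matches, CAS.
#'
#' @param ids data.frame from [identify_compounds()]
#' @param path output CSV
#' @export
write_identification_table <- function(ids, path) {
  cols <- c("candidate_id", "name", "rt_s", "quant_mz", "forward_match",
            "reverse_match", "identified", "cas", "n_fragments")
  write.csv(ids[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
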