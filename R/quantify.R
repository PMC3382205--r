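# Reference-normalized relative quantification: the quantification-ion
# signal of each compound is divided by the mean signal of the same day's
# pooled reference injections and log2-transformed, which cancels per-day
# multiplicative drift (fiber aging, detector response).

#' Quantify compounds as log2 ratios to the daily reference
#'
#' For compound c in biological sample s,
#' `value = log2(max(signal, floor) / max(ref, floor))`, where `signal` is
#' the quantification-ion intensity, `ref` is the mean quantification-ion
#' intensity over the reference injections run on the same analysis day as
#' s, and `floor` is the 1st percentile of all positive intensities in the
#' table (missing values are treated as below the floor). Because sample and
#' reference share the day's multiplicative drift factor, the ratio is
#' drift-invariant.
#'
#' @param table the [fragment_table()] (pre- or post-filtering; only
#'   quantification-ion rows are read)
#' @param ids identification table from [identify_compounds()] (needs
#'   `candidate_id`, `name`, `quant_mz`, `quant_fragment_id`, `rt_s`)
#' @param floor_quantile quantile of positive intensities used as the floor
#' @return a [compound_table()] over the biological samples
#' @export
quantify_compounds <- function(table, ids, floor_quantile = 0.01) {
  bio <- table$samples[table$samples$role == "biological", ]
  refs <- table$samples[table$samples$role == "reference", ]
  missing_days <- setdiff(unique(bio$day), unique(refs$day))
  if (length(missing_days))
    stop_vocnet(paste("no reference sample on day(s):",
                      paste(sort(missing_days), collapse = ", ")),
                "vocnet_no_reference")
  pos <- table$matrix[table$matrix > 0 & !is.na(table$matrix)]
  floor <- as.numeric(quantile(pos, floor_quantile, na.rm = TRUE))

  sig <- table$matrix[ids$quant_fragment_id, bio$sample_id, drop = FALSE]
  refmat <- table$matrix[ids$quant_fragment_id, refs$sample_id, drop = FALSE]
  days <- sort(unique(bio$day))
  ref_by_day <- vapply(days, function(d)
    rowMeans(refmat[, refs$day == d, drop = FALSE], na.rm = TRUE),
    numeric(nrow(refmat)))
  if (is.null(dim(ref_by_day)))
    ref_by_day <- matrix(ref_by_day, nrow = nrow(refmat))
  colnames(ref_by_day) <- days

  sig[is.na(sig)] <- 0
  ref_expanded <- ref_by_day[, as.character(bio$day), drop = FALSE]
  ref_expanded[is.na(ref_expanded)] <- 0
  values <- log2(pmax(sig, floor) / pmax(ref_expanded, floor))
  colnames(values) <- bio$sample_id

  compound_table(
    compounds = data.frame(candidate_id = ids$candidate_id,
                           name = ids$name, quant_mz = ids$quant_mz,
                           rt_s = ids$rt_s, stringsAsFactors = FALSE),
    values = values, floor_used = floor)
}
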