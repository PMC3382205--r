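#' @importFrom stats median quantile rnorm runif setNames aggregate
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

SAMPLE_ROLES <- c("biological", "reference", "blank")
TREATMENTS <- c("at_harvest", "shelf_life")
MZ_RANGE <- c(35L, 220L)

stop_vocnet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vocnet_error")))
}

#' Construct an aligned fragment table
#'
#' The central container of the pipeline: a fragments x samples intensity
#' matrix (one row per aligned molecular fragment, i.e. one m/z at a
#' retention time) together with per-fragment annotation and per-sample
#' metadata. Emulates the wide layout exported by alignment software.
#'
#' @param fragments data.frame with columns `fragment_id` (unique),
#'   `mz` (integer, within the 35--220 scan range) and `rt_s`
#'   (retention time, seconds).
#' @param samples data.frame with columns `sample_id` (unique), `role`
#'   (`"biological"`, `"reference"` or `"blank"`), `genotype`, `location`,
#'   `maturity_stage` (1--4, may be `NA` for references/blanks),
#'   `treatment` (`"at_harvest"`/`"shelf_life"`, may be `NA`) and `day`
#'   (positive integer analysis-batch day, required for every sample).
#' @param matrix numeric matrix, `nrow(fragments)` x `nrow(samples)`;
#'   `NA` encodes "not detected" (below the detection floor).
#' @return An object of class `fragment_table`.
#' @export
fragment_table <- function(fragments, samples, matrix) {
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"

  if (anyDuplicated(fragments$fragment_id))
    stop_vocnet("duplicate fragment_id in fragment table",
                "vocnet_duplicate_fragment")
  bad_mz <- fragments$mz < MZ_RANGE[1] | fragments$mz > MZ_RANGE[2]
  if (any(bad_mz))
    stop_vocnet(sprintf("m/z outside scan range [%d, %d]: %s",
                        MZ_RANGE[1], MZ_RANGE[2],
                        paste(fragments$fragment_id[bad_mz], collapse = ", ")),
                "vocnet_mz_out_of_range")
  if (anyDuplicated(samples$sample_id))
    stop_vocnet("duplicate sample_id in metadata", "vocnet_duplicate_sample")
  if (!all(samples$role %in% SAMPLE_ROLES))
    stop_vocnet("sample role must be biological, reference or blank",
                "vocnet_bad_role")
  if (any(is.na(samples$day)) || any(samples$day < 1))
    stop_vocnet("every sample needs a positive analysis day",
                "vocnet_missing_day")
  if (nrow(matrix) != nrow(fragments) || ncol(matrix) != nrow(samples))
    stop_vocnet("matrix dimensions do not match fragment/sample lists",
                "vocnet_dim_mismatch")
  if (any(matrix < 0, na.rm = TRUE) || any(is.infinite(matrix)))
    stop_vocnet("intensities must be finite and nonnegative",
                "vocnet_bad_intensity")

  rownames(matrix) <- fragments$fragment_id
  colnames(matrix) <- samples$sample_id
  rownames(fragments) <- NULL
  rownames(samples) <- NULL
  fragments$rt_s <- round(fragments$rt_s, 1)  # 0.1 s storage precision
  fragments$mz <- as.integer(fragments$mz)
  structure(list(fragments = fragments, samples = samples, matrix = matrix),
            class = "fragment_table")
}

#' @export
print.fragment_table <- function(x, ...) {
  tab <- table(factor(x$samples$role, levels = SAMPLE_ROLES))
  cat(sprintf(
    "fragment_table: %d fragments x %d samples (%d biological, %d reference, %d blank)\n",
    nrow(x$fragments), nrow(x$samples),
    tab[["biological"]], tab[["reference"]], tab[["blank"]]))
  invisible(x)
}

#' @export
dim.fragment_table <- function(x) dim(x$matrix)

role_columns <- function(table, roles) {
  table$samples$sample_id[table$samples$role %in% roles]
}

#' Read an aligned fragment table and its sample metadata
#'
#' @param path TSV file: columns `fragment_id`, `mz`, `rt_s`, then one
#'   column per sample. Empty cells and `NA` are read as missing.
#' @param metadata_path CSV file mapping `sample_id` to role, genotype,
#'   location, maturity_stage, treatment and day.
#' @return A [fragment_table()].
#' @export
read_fragment_table <- function(path, metadata_path) {
  raw <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 4 ||
      !identical(names(raw)[1:3], c("fragment_id", "mz", "rt_s")))
    stop_vocnet("fragment table must start with fragment_id, mz, rt_s",
                "vocnet_bad_header")
  meta <- read.csv(metadata_path, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  sample_ids <- names(raw)[-(1:3)]
  unknown <- setdiff(sample_ids, meta$sample_id)
  if (length(unknown))
    stop_vocnet(paste("sample ids missing from metadata:",
                      paste(unknown, collapse = ", ")),
                "vocnet_unknown_sample")
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- as.matrix(raw[, -(1:3), drop = FALSE])
  fragment_table(raw[, 1:3], meta, mat)
}

#' Write an aligned fragment table (and optionally its metadata)
#'
#' Missing values are written as empty cells. `read_fragment_table()` on the
#' written files reproduces the table exactly (round-trip identity).
#'
#' @param table a [fragment_table()]
#' @param path output TSV path
#' @param metadata_path optional CSV path for the sample metadata
#' @export
write_fragment_table <- function(table, path, metadata_path = NULL) {
  out <- cbind(table$fragments[, c("fragment_id", "mz", "rt_s")],
               as.data.frame(table$matrix, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  if (!is.null(metadata_path))
    write.csv(table$samples, metadata_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trait table
#'
#' Fruit-quality traits per biological sample: `colour_index`
#' (dimensionless, 1000a/(L b)), `firmness` (kgf), `weight` (g) and
#' `ssc` (soluble solids content, degrees Brix).
#'
#' @param path CSV with columns `sample_id`, `colour_index`, `firmness`,
#'   `weight`, `ssc`.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  traits <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  needed <- c("sample_id", "colour_index", "firmness", "weight", "ssc")
  if (!all(needed %in% names(traits)))
    stop_vocnet("trait table must have sample_id, colour_index, firmness, weight, ssc",
                "vocnet_bad_header")
  for (v in c("firmness", "weight", "ssc"))
    if (any(traits[[v]] < 0, na.rm = TRUE))
      stop_vocnet(sprintf("%s must be nonnegative", v), "vocnet_bad_trait")
  traits
}

#' @rdname read_trait_table
#' @param traits data.frame as returned by [read_trait_table()]
#' @export
write_trait_table <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- MSP spectral libraries -------------------------------------------------

new_spectrum_entry <- function(name, peaks, cas = NA_character_) {
  if (!length(peaks))
    stop_vocnet(sprintf("spectrum '%s' has no peaks", name),
                "vocnet_empty_spectrum")
  peaks <- peaks / max(peaks) * 999  # base peak scaled to 999
  structure(list(name = name, cas = cas, peaks = peaks),
            class = "spectrum_entry")
}

#' @export
print.spectrum_entry <- function(x, ...) {
  cat(sprintf("spectrum_entry '%s' (%d peaks, base m/z %s)\n",
              x$name, length(x$peaks),
              names(x$peaks)[which.max(x$peaks)]))
  invisible(x)
}

#' Read an MSP spectral library
#'
#' Parses standard NIST-style MSP records (`Name:`, optional `CAS#:`,
#' `Num Peaks:` followed by m/z intensity pairs separated by `;` or
#' whitespace). Each entry is normalized so that its base peak has
#' relative intensity exactly 999.
#'
#' @param path MSP file
#' @return list of `spectrum_entry` objects (fields `name`, `cas`, `peaks`:
#'   a numeric vector named by integer m/z).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  name <- NULL; cas <- NA_character_; npeaks <- NA_integer_
  mzs <- numeric(); ints <- numeric()
  flush <- function() {
    if (is.null(name)) return()
    if (!is.na(npeaks) && npeaks != length(mzs))
      stop_vocnet(sprintf("'%s': Num Peaks says %d but %d parsed",
                          name, npeaks, length(mzs)),
                  "vocnet_msp_num_peaks")
    entries[[length(entries) + 1L]] <<-
      new_spectrum_entry(name, setNames(ints, as.integer(mzs)), cas)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") { flush(); name <- NULL; cas <- NA_character_
                    npeaks <- NA_integer_; mzs <- numeric(); ints <- numeric()
                    next }
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush(); name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      cas <- NA_character_; npeaks <- NA_integer_
      mzs <- numeric(); ints <- numeric()
    } else if (grepl("^CAS#?:", ln, ignore.case = TRUE)) {
      cas <- trimws(sub("^CAS#?:", "", ln, ignore.case = TRUE))
    } else if (grepl("^Num ?Peaks:", ln, ignore.case = TRUE)) {
      npeaks <- as.integer(trimws(sub("^Num ?Peaks:", "", ln,
                                      ignore.case = TRUE)))
    } else if (grepl(":", ln, fixed = TRUE) && !grepl("^[0-9]", ln)) {
      next  # other header fields (Formula:, MW:, Comments:) are ignored
    } else {
      nums <- as.numeric(strsplit(ln, "[;,[:space:]]+")[[1]])
      nums <- nums[!is.na(nums)]
      if (length(nums) %% 2 != 0)
        stop_vocnet("malformed peak line in MSP record", "vocnet_msp_peaks")
      mzs <- c(mzs, nums[seq(1, length(nums), by = 2)])
      ints <- c(ints, nums[seq(2, length(nums), by = 2)])
    }
  }
  flush()
  entries
}

#' Write spectra to an MSP file
#'
#' @param spectra list of `spectrum_entry` (or [assemble_spectrum()]
#'   pseudo-spectra, which are coerced)
#' @param path output path
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    nm <- if (!is.null(sp$name)) sp$name else sp$candidate_id
    writeLines(sprintf("Name: %s", nm), con)
    if (!is.null(sp$cas) && !is.na(sp$cas))
      writeLines(sprintf("CAS#: %s", sp$cas), con)
    if (!is.null(sp$rt_s))
      writeLines(sprintf("Comments: rt_s=%g", sp$rt_s), con)
    writeLines(sprintf("Num Peaks: %d", length(sp$peaks)), con)
    writeLines(paste(sprintf("%s %g", names(sp$peaks), unname(sp$peaks)),
                     collapse = "; "), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- Compound tables --------------------------------------------------------

#' Construct a compound table
#'
#' Compounds x biological-samples matrix of log2 relative abundances
#' (signal over the same-day pooled reference).
#'
#' @param compounds data.frame with columns `candidate_id`, `name`,
#'   `quant_mz`, `rt_s`
#' @param values numeric matrix, compounds x biological samples
#' @param floor_used detection floor applied before forming ratios
#' @return object of class `compound_table`
#' @export
compound_table <- function(compounds, values, floor_used = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(compounds))
    stop_vocnet("values rows must match compounds", "vocnet_dim_mismatch")
  if (any(!is.finite(values)))
    stop_vocnet("compound table values must be finite", "vocnet_bad_intensity")
  rownames(values) <- compounds$candidate_id
  structure(list(compounds = as.data.frame(compounds), values = values,
                 floor_used = floor_used),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d compounds x %d samples (log2 vs daily reference)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.compound_table <- function(x) dim(x$values)

#' Write a compound table to CSV
#'
#' Rows are ordered by retention time, ties broken by name, so output is
#' deterministic. Columns: `candidate_id`, `name`, `quant_mz`, `rt_s`,
#' then one column per biological sample.
#'
#' @param table a [compound_table()]
#' @param path output CSV
#' @export
write_compound_table <- function(table, path) {
  ord <- order(table$compounds$rt_s, table$compounds$name)
  cmp <- table$compounds[ord, c("candidate_id", "name", "quant_mz", "rt_s")]
  vals <- round(table$values[ord, , drop = FALSE], 6)
  out <- cbind(cmp, as.data.frame(vals, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_compound_table
#' @export
read_compound_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  compound_table(raw[, c("candidate_id", "name", "quant_mz", "rt_s")],
                 as.matrix(raw[, -(1:4), drop = FALSE]))
}
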