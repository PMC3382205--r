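# Synthetic GC-MS volatile experiment generator.
#
# Abundances follow a latent-factor model on the log2 scale: a ripening
# factor shared by all samples (increases with maturity stage and shelf-life
# treatment) plus one co-regulation factor per chemical group, so compound
# groups emerge as correlated blocks and lactones/lipid-derived volatiles are
# anticorrelated through opposite-signed ripening loadings.

COMPOUND_GROUPS <- c("lactone", "linear_ester", "lipid_derived", "terpenoid",
                     "carboxylic_acid", "long_chain_aldehyde", "other")

# default proportions of compounds per group (rescaled to n_compounds)
GROUP_WEIGHTS <- c(lactone = 8, linear_ester = 6, lipid_derived = 10,
                   terpenoid = 10, carboxylic_acid = 6,
                   long_chain_aldehyde = 4, other = 16)

# ripening-loading ranges per group (log2 units per unit latent score).
# One group-level loading is drawn from the range and compounds scatter
# tightly around it: a planted group is a genuinely co-regulated unit.
# Lactones load positively, lipid-derived ("green note") volatiles
# negatively -- this plants the inter-group anticorrelation.
RIPENING_RANGES <- list(
  lactone = c(1.2, 1.8), linear_ester = c(0.5, 0.9),
  lipid_derived = c(-1.8, -1.2), terpenoid = c(-0.5, 0.5),
  carboxylic_acid = c(-0.4, 0.4), long_chain_aldehyde = c(-0.2, 0.2),
  other = c(-0.5, 0.5))
RIPENING_WITHIN_SD <- 0.15  # half-width of within-group loading jitter

POLYSILOXANE_MZ <- c(73L, 147L, 207L, 208L, 221L, 281L)

# siloxane ions inside the 35-220 scan range; the full flagging series above
# includes masses the instrument never records here
PLANTED_CONTAM_MZ <- c(73L, 147L, 207L, 208L)

#' Experimental design for the synthetic generator
#'
#' @param conditions data.frame with columns `genotype`, `location`,
#'   `stage` (1--4), `treatment` and `n_fruits` (biological replicates for
#'   that cell). Totals are reproduced exactly.
#' @param n_reference number of pooled reference injections (one per
#'   analysis day by default)
#' @param n_blank number of blank injections
#' @param n_days number of analysis-batch days; drift correction keys on the
#'   day, and references are spread across days round-robin
#' @param seed integer seed; the same seed yields byte-identical output
#' @return object of class `voc_design`
#' @seealso [peach_design()] for the default multi-genotype layout
#' @export
design_config <- function(conditions, n_reference = 12, n_blank = 5,
                          n_days = 12, seed = 1) {
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  needed <- c("genotype", "location", "stage", "treatment", "n_fruits")
  if (!all(needed %in% names(conditions)))
    stop_vocnet("conditions needs genotype, location, stage, treatment, n_fruits",
                "vocnet_bad_design")
  if (sum(conditions$n_fruits) < 1 || n_days < 1)
    stop_vocnet("design yields zero samples", "vocnet_bad_design")
  if (!all(conditions$treatment %in% TREATMENTS))
    stop_vocnet("treatment must be at_harvest or shelf_life",
                "vocnet_bad_design")
  structure(list(conditions = conditions, n_reference = n_reference,
                 n_blank = n_blank, n_days = n_days, seed = as.integer(seed)),
            class = "voc_design")
}

#' Default stone-fruit experimental design
#'
#' Four genotypes (two of them followed over four maturity stages, one grown
#' in two locations), each condition analyzed at harvest and after a
#' shelf-life simulation: 22 condition cells holding 3--4 fruits each, for
#' 85 biological samples, plus 12 daily pooled references and 5 blanks --
#' 102 chromatograms in total.
#'
#' @inheritParams design_config
#' @export
peach_design <- function(seed = 1) {
  cells <- rbind(
    expand.grid(genotype = "Granada", location = "Murcia", stage = 1:4,
                stringsAsFactors = FALSE),
    expand.grid(genotype = "MxR_01", location = "Murcia", stage = 1:4,
                stringsAsFactors = FALSE),
    data.frame(genotype = "MxR_01", location = "Valencia", stage = 4),
    data.frame(genotype = "Maruja", location = "Murcia", stage = 4),
    data.frame(genotype = "RedCandem", location = "Murcia", stage = 4))
  conditions <- merge(cells, data.frame(treatment = TREATMENTS),
                      by = NULL)
  conditions$n_fruits <- 4L
  # three shelf-life cells carry 3 fruits so the design totals 85
  drop_one <- conditions$treatment == "shelf_life" &
    (conditions$genotype %in% c("Maruja", "RedCandem") |
       (conditions$genotype == "MxR_01" & conditions$location == "Valencia"))
  conditions$n_fruits[drop_one] <- 3L
  design_config(conditions, n_reference = 12, n_blank = 5, n_days = 12,
                seed = seed)
}

#' Noise model for the synthetic generator
#'
#' @param sigma_log sd (log2 units) of multiplicative noise, applied both to
#'   per-sample compound abundances and to per-fragment rendered intensities
#' @param drift_per_day multiplicative sensitivity factor per analysis day
#'   (fiber aging / system drift); `NULL` means `0.97^(day-1)`
#' @param baseline_sd additive baseline noise scale (intensity units)
#' @param peak_threshold_factor detection floor = factor x `baseline_sd`;
#'   rendered intensities below the floor are reported missing
#' @param rt_jitter_s sd (s) of per-fragment retention-time jitter; keep it
#'   well below half the clustering window
#' @return object of class `noise_config`
#' @export
noise_config <- function(sigma_log = 0.15, drift_per_day = NULL,
                         baseline_sd = 40, peak_threshold_factor = 10,
                         rt_jitter_s = 0.5) {
  stopifnot(sigma_log >= 0, baseline_sd >= 0, peak_threshold_factor >= 0,
            rt_jitter_s >= 0)
  structure(list(sigma_log = sigma_log, drift_per_day = drift_per_day,
                 baseline_sd = baseline_sd,
                 peak_threshold_factor = peak_threshold_factor,
                 rt_jitter_s = rt_jitter_s),
            class = "noise_config")
}

day_drift <- function(noise, n_days) {
  if (is.null(noise$drift_per_day)) 0.97^(seq_len(n_days) - 1)
  else rep_len(noise$drift_per_day, n_days)
}

build_samples <- function(design) {
  cond <- design$conditions
  bio <- cond[rep(seq_len(nrow(cond)), cond$n_fruits), , drop = FALSE]
  n_bio <- nrow(bio)
  bio <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_bio)),
    role = "biological",
    genotype = bio$genotype, location = bio$location,
    maturity_stage = bio$stage, treatment = bio$treatment,
    day = ((seq_len(n_bio) - 1L) %% design$n_days) + 1L,
    stringsAsFactors = FALSE)
  refs <- data.frame(
    sample_id = sprintf("REF%02d", seq_len(design$n_reference)),
    role = "reference", genotype = NA, location = NA,
    maturity_stage = NA, treatment = NA,
    day = ((seq_len(design$n_reference) - 1L) %% design$n_days) + 1L)
  blk_days <- unique(round(seq(1, design$n_days,
                               length.out = max(design$n_blank, 1))))
  blanks <- data.frame(
    sample_id = sprintf("BLK%02d", seq_len(design$n_blank)),
    role = "blank", genotype = NA, location = NA,
    maturity_stage = NA, treatment = NA,
    day = rep_len(blk_days, design$n_blank))
  rbind(bio, refs, blanks)
}

#' Generate ground-truth compounds, abundances and traits
#'
#' Builds the latent-factor truth behind a synthetic experiment: compound
#' definitions (retention time, fragment pattern, chemical group, loadings),
#' a per-sample latent ripening score, the true log2 abundance matrix,
#' contaminant fragments, and ripening-linked fruit-quality traits.
#'
#' The log2 abundance of compound c in biological sample s is
#' `base_c + ripening_loading_c * rho_s + group_loading_c * g[G(c), s]
#'  + genotype effect + N(0, sigma_log)`,
#' where `rho_s` increases with maturity stage and shelf-life treatment and
#' `g` holds one independent standard-normal factor per chemical group and
#' sample. Traits are driven by the same `rho`: colour index increases,
#' firmness decreases, weight and soluble solids are weakly coupled.
#'
#' @param design a [design_config()]
#' @param noise a [noise_config()]
#' @param n_compounds number of true compounds (at least one per group)
#' @param n_contaminants number of blank-borne contaminant fragments
#'   (polysiloxane-series m/z values)
#' @return object of class `ground_truth`: `compounds`, `patterns`,
#'   `fragment_map` (fragment -> compound partition), `contaminants`,
#'   `rho`, `abundance` (log2, compounds x biological samples), `traits`,
#'   `samples`.
#' @export
generate_truth <- function(design, noise = noise_config(),
                           n_compounds = 60, n_contaminants = 8) {
  if (n_compounds < length(COMPOUND_GROUPS))
    stop_vocnet("need at least one compound per chemical group",
                "vocnet_bad_design")
  set.seed(design$seed)
  samples <- build_samples(design)
  bio <- samples[samples$role == "biological", ]
  n_bio <- nrow(bio)
  if (n_bio == 0) stop_vocnet("design yields zero biological samples",
                              "vocnet_bad_design")

  # group sizes proportional to the default weights, every group represented
  sizes <- pmax(round(GROUP_WEIGHTS / sum(GROUP_WEIGHTS) * n_compounds), 1)
  while (sum(sizes) != n_compounds) {
    i <- if (sum(sizes) > n_compounds) which.max(sizes) else which.min(sizes)
    sizes[i] <- sizes[i] + sign(n_compounds - sum(sizes))
  }
  group <- rep(names(sizes), sizes)

  compounds <- data.frame(
    name = sprintf("%s_%02d", group, unlist(lapply(sizes, seq_len))),
    group = group, stringsAsFactors = FALSE)
  # retention times: spread over the chromatogram with jitter, so true
  # compounds are separated by much more than the clustering window
  base_rt <- seq(150, 2250, length.out = n_compounds)
  compounds$rt_s <- round(sample(base_rt + runif(n_compounds, -10, 10)), 1)
  group_rl <- vapply(names(sizes), function(g) {
    r <- RIPENING_RANGES[[g]]; runif(1, r[1], r[2])
  }, numeric(1))
  compounds$ripening_loading <- group_rl[group] +
    runif(n_compounds, -RIPENING_WITHIN_SD, RIPENING_WITHIN_SD)
  compounds$group_loading <- runif(n_compounds, 0.8, 1.1)
  compounds$base_log2 <- runif(n_compounds, 14, 19)

  # fragment patterns: 3-8 fragments, distinct unit-resolution m/z,
  # base peak 999
  patterns <- lapply(seq_len(n_compounds), function(i) {
    nf <- sample(3:8, 1)
    mz <- sample(MZ_RANGE[1]:MZ_RANGE[2], nf)
    ints <- c(999, round(runif(nf - 1, 50, 950)))
    setNames(as.numeric(ints), mz)
  })
  names(patterns) <- compounds$name

  # latent ripening score per biological sample
  rho <- (bio$maturity_stage - 2.5) +
    0.7 * (bio$treatment == "shelf_life") + rnorm(n_bio, 0, 0.15)
  names(rho) <- bio$sample_id

  genotypes <- unique(bio$genotype)
  geno_eff <- matrix(rnorm(n_compounds * length(genotypes), 0, 0.3),
                     n_compounds, length(genotypes),
                     dimnames = list(compounds$name, genotypes))
  group_factors <- matrix(rnorm(length(COMPOUND_GROUPS) * n_bio),
                          length(COMPOUND_GROUPS), n_bio,
                          dimnames = list(COMPOUND_GROUPS, bio$sample_id))

  abundance <- compounds$base_log2 +
    outer(compounds$ripening_loading, rho) +
    compounds$group_loading * group_factors[compounds$group, , drop = FALSE] +
    geno_eff[, match(bio$genotype, genotypes), drop = FALSE] +
    matrix(rnorm(n_compounds * n_bio, 0, noise$sigma_log), n_compounds)
  dimnames(abundance) <- list(compounds$name, bio$sample_id)

  # fragment identities, ordered by (jittered) retention time like an
  # aligned export would be
  frag <- data.frame(
    compound = rep(compounds$name, lengths(patterns)),
    mz = as.integer(unlist(lapply(patterns, names))),
    rel_int = unname(unlist(patterns)),
    rt_s = round(rep(compounds$rt_s, lengths(patterns)) +
                   rnorm(sum(lengths(patterns)), 0, noise$rt_jitter_s), 1),
    stringsAsFactors = FALSE)
  contam <- data.frame(
    compound = rep(NA_character_, n_contaminants),
    mz = rep_len(PLANTED_CONTAM_MZ, n_contaminants),
    rel_int = rep(NA_real_, n_contaminants),
    rt_s = round(runif(n_contaminants, 100, 2300), 1),
    base_log2 = runif(n_contaminants, 13.5, 16))
  frag_all <- rbind(frag[, c("compound", "mz", "rel_int", "rt_s")],
                    contam[, c("compound", "mz", "rel_int", "rt_s")])
  ord <- order(frag_all$rt_s, frag_all$mz)
  frag_all <- frag_all[ord, ]
  frag_all$fragment_id <- sprintf("F%04d", seq_len(nrow(frag_all)))
  contam_ids <- frag_all$fragment_id[is.na(frag_all$compound)]
  contam$fragment_id <- contam_ids[match(
    paste(contam$rt_s, contam$mz),
    paste(frag_all$rt_s[is.na(frag_all$compound)],
          frag_all$mz[is.na(frag_all$compound)]))]
  rownames(frag_all) <- frag_all$fragment_id

  traits <- data.frame(
    sample_id = bio$sample_id,
    colour_index = round(1 + 4.5 * rho + rnorm(n_bio, 0, 1.2), 2),
    firmness = round(pmax(0.2, 4.2 - 1.5 * rho + rnorm(n_bio, 0, 0.4)), 2),
    weight = round(pmax(60, 160 + 15 * rho + rnorm(n_bio, 0, 20)), 1),
    ssc = round(pmax(5, 11 + 0.8 * rho + rnorm(n_bio, 0, 1.2)), 1),
    stringsAsFactors = FALSE)

  structure(list(compounds = compounds, patterns = patterns,
                 fragment_map = frag_all[!is.na(frag_all$compound),
                                         c("fragment_id", "compound", "mz",
                                           "rel_int", "rt_s")],
                 fragments = frag_all, contaminants = contam,
                 rho = rho, abundance = abundance, traits = traits,
                 samples = samples, design = design, noise = noise),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d compounds (%d fragments + %d contaminants), %d samples\n",
    nrow(x$compounds), nrow(x$fragment_map), nrow(x$contaminants),
    nrow(x$samples)))
  invisible(x)
}

#' Render an aligned fragment table from ground truth
#'
#' Fragment intensity = compound abundance x pattern fraction x day drift x
#' multiplicative log-normal noise, plus additive baseline noise; values
#' below the detection floor (`peak_threshold_factor * baseline_sd`) are set
#' missing. Blanks contain only contaminants and baseline; references carry
#' the all-biological-sample mean profile (a pooled mix), subject to the same
#' drift and noise.
#'
#' @param truth a [generate_truth()] result
#' @param noise override the noise configuration stored in `truth`
#' @return list with elements `table` (a [fragment_table()]), `traits`
#'   (trait data.frame) and `metadata` (sample data.frame)
#' @export
render_fragment_table <- function(truth, noise = truth$noise) {
  design <- truth$design
  set.seed(design$seed + 1L)
  samples <- truth$samples
  frag <- truth$fragments
  n_frag <- nrow(frag)
  n_smp <- nrow(samples)
  drift <- day_drift(noise, design$n_days)[samples$day]
  floor <- noise$peak_threshold_factor * noise$baseline_sd

  lin_ab <- 2^truth$abundance                       # compounds x biological
  ref_profile <- rowMeans(lin_ab)                   # pooled mix of all samples

  mat <- matrix(NA_real_, n_frag, n_smp,
                dimnames = list(frag$fragment_id, samples$sample_id))
  is_contam <- is.na(frag$compound)
  comp_idx <- match(frag$compound, rownames(lin_ab))
  contam_base <- 2^truth$contaminants$base_log2[
    match(frag$fragment_id[is_contam], truth$contaminants$fragment_id)]

  for (j in seq_len(n_smp)) {
    role <- samples$role[j]
    signal <- numeric(n_frag)
    if (role == "biological") {
      signal[!is_contam] <- lin_ab[comp_idx[!is_contam], j] *
        frag$rel_int[!is_contam] / 999
    } else if (role == "reference") {
      signal[!is_contam] <- ref_profile[comp_idx[!is_contam]] *
        frag$rel_int[!is_contam] / 999
    }
    signal[is_contam] <- contam_base
    fragnoise <- 2^rnorm(n_frag, 0, noise$sigma_log)
    value <- signal * drift[j] * fragnoise + rnorm(n_frag, 0, noise$baseline_sd)
    value[value <= floor | value <= 0] <- NA_real_
    mat[, j] <- value
  }

  table <- fragment_table(
    frag[, c("fragment_id", "mz", "rt_s")], samples, mat)
  list(table = table, traits = truth$traits, metadata = samples)
}

#' Build a spectral library from ground truth
#'
#' Converts a fraction of the planted compound patterns into normalized
#' library entries, emulating a reference library that covers only part of
#' the volatile complement (the remainder end up labelled `Ni_NN`
#' downstream). Coverage keeps the first `coverage` fraction of compounds
#' in retention-time order, so the selection is deterministic.
#'
#' @param truth a [generate_truth()] result
#' @param coverage fraction of compounds present in the library
#' @return list of `spectrum_entry`
#' @export
truth_library <- function(truth, coverage = 0.8) {
  keep <- order(truth$compounds$rt_s)[
    seq_len(floor(coverage * nrow(truth$compounds)))]
  lapply(keep, function(i)
    new_spectrum_entry(truth$compounds$name[i], truth$patterns[[i]]))
}

#' Hunter colour index
#'
#' `IC = 1000 a / (L b)`: negative for green peel, increasingly positive as
#' ground colour turns orange-red during ripening.
#'
#' @param L,a,b Hunter colorimeter readings; `L` must be positive and `b`
#'   nonzero
#' @return numeric colour index
#' @export
colour_index <- function(L, a, b) {
  if (any(L <= 0)) stop_vocnet("Hunter L must be positive", "vocnet_bad_colour")
  if (any(b == 0)) stop_vocnet("Hunter b must be nonzero", "vocnet_bad_colour")
  1000 * a / (L * b)
}

#' Write ground truth to JSON
#'
#' Exports the scoring-relevant parts of a [generate_truth()] object
#' (fragment -> compound map, contaminant ids, group labels, latent ripening
#' scores) for use outside R.
#'
#' @param truth a [generate_truth()] result
#' @param path output JSON path
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    fragment_map = truth$fragment_map[, c("fragment_id", "compound")],
    contaminant_fragments = truth$contaminants$fragment_id,
    groups = truth$compounds[, c("name", "group")],
    rho = as.list(truth$rho))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
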