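# End-to-end orchestration: contaminant filtering -> fragment clustering ->
# pseudo-spectrum assembly and identification -> reference-normalized
# quantification -> correlation network and trait tables, with a run report
# and a scorer against synthetic ground truth.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Unknown arguments are rejected (there are no `...`).
#'
#' @param r_min,rt_window_s,min_overlap,keep_singletons see [cluster_params()]
#' @param mz_list polysiloxane m/z series, see [flag_polysiloxane()]
#' @param blank_fraction,intensity_fraction see [flag_blank_present()]
#' @param match_min,co_elution_window_s see [identify_compounds()]
#' @param floor_quantile see [quantify_compounds()]
#' @param hi_cut,lo_cut,strong_cut see [build_network()]
#' @param cut_height see [metabolite_hca()]
#' @param k,alpha see [trait_correlations()]
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(r_min = 0.8, rt_window_s = 3, min_overlap = 10,
                            keep_singletons = TRUE,
                            mz_list = POLYSILOXANE_MZ,
                            blank_fraction = 0.5, intensity_fraction = 0.1,
                            match_min = 800, co_elution_window_s = 9,
                            floor_quantile = 0.01,
                            hi_cut = 0.6, lo_cut = -0.6, strong_cut = 0.7,
                            cut_height = 0.4, k = 9, alpha = 0.05) {
  stopifnot(r_min > 0, r_min < 1, rt_window_s > 0,
            blank_fraction >= 0, blank_fraction <= 1,
            intensity_fraction >= 0, match_min >= 0, match_min <= 1000,
            hi_cut > 0, lo_cut < 0, alpha > 0, alpha < 1, k >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Identified/unidentified bookkeeping
#'
#' Arithmetic used in run reports: total candidates and, when an
#' independently (manually) established compound count is available, the
#' percentage of it that the automated pipeline detected.
#'
#' @param n_identified,n_unidentified candidate counts by identification
#'   outcome
#' @param n_manual total compounds found by manual chromatogram inspection
#'   (optional)
#' @return list: `candidates`, `detection_pct` (rounded to whole percent,
#'   `NA` when `n_manual` is missing)
#' @export
detection_summary <- function(n_identified, n_unidentified, n_manual = NA) {
  candidates <- n_identified + n_unidentified
  list(candidates = candidates,
       detection_pct = if (is.na(n_manual)) NA_real_
       else round(100 * candidates / n_manual))
}

#' Run the full reconstruction pipeline
#'
#' @param table an aligned [fragment_table()]
#' @param library spectral library ([read_msp()] entries)
#' @param traits optional trait data.frame
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, every stage output is
#'   written there (CSV/MSP/GraphML/SIF/JSON) deterministically
#' @return object of class `voc_run`: stage outputs (`contaminants`,
#'   `filtered`, `corr_fragments`, `clusters`, `spectra`, `ids`,
#'   `compound_table`, `corr_metabolites`, `hca`, `network`,
#'   `trait_tables`) plus a `report` of per-stage counts and the config
#'   echo.
#' @export
run_pipeline <- function(table, library, traits = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  cp <- cluster_params(config$r_min, config$rt_window_s, config$min_overlap,
                       config$keep_singletons)

  rep_poly <- flag_polysiloxane(table, config$mz_list)
  rep_blank <- flag_blank_present(table, config$blank_fraction,
                                  config$intensity_fraction)
  filtered <- drop_flagged(table, list(rep_poly, rep_blank))

  corr_frag <- fragment_correlations(filtered, cp)
  clusters <- cluster_fragments(filtered, corr_frag, cp)
  spectra <- assemble_spectra(clusters, filtered)
  ids <- identify_compounds(spectra, library, config$match_min,
                            config$co_elution_window_s)
  ct <- quantify_compounds(filtered, ids, config$floor_quantile)

  corr_met <- metabolite_correlations(ct)
  hca <- metabolite_hca(corr_met, config$cut_height)
  network <- build_network(corr_met, config$hi_cut, config$lo_cut,
                           config$strong_cut)
  trait_tables <- if (!is.null(traits))
    trait_correlations(ct, traits, config$k, config$alpha)

  edge_sign <- if (igraph::ecount(network))
    igraph::E(network)$sign else character(0)
  report <- list(
    chromatograms = nrow(table$samples),
    fragments_in = nrow(table$fragments),
    fragments_flagged = length(unique(c(rep_poly$flagged$fragment_id,
                                        rep_blank$flagged$fragment_id))),
    fragments_out = nrow(filtered$fragments),
    clusters = nrow(clusters$clusters),
    identified = sum(ids$identified),
    unidentified = sum(!ids$identified),
    pairs_evaluated = corr_met$n_pairs,
    edges = length(edge_sign),
    edges_positive = sum(edge_sign == "positive"),
    edges_negative = sum(edge_sign == "negative"),
    config = unclass(config))
  stopifnot(report$identified + report$unidentified == report$clusters)

  run <- structure(list(contaminants = list(polysiloxane = rep_poly,
                                            blank_present = rep_blank),
                        filtered = filtered, corr_fragments = corr_frag,
                        clusters = clusters, spectra = spectra, ids = ids,
                        compound_table = ct, corr_metabolites = corr_met,
                        hca = hca, network = network,
                        trait_tables = trait_tables, report = report),
                   class = "voc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.voc_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "voc_run: %d chromatograms, %d fragments (%d contaminant-flagged)\n",
    "  %d candidate compounds: %d identified, %d unidentified\n",
    "  %d metabolite pairs evaluated; network: %d edges (%d+/%d-)\n"),
    r$chromatograms, r$fragments_in, r$fragments_flagged,
    r$clusters, r$identified, r$unidentified,
    r$pairs_evaluated, r$edges, r$edges_positive, r$edges_negative))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_contaminant_report(run$contaminants, p("contaminants.csv"))
  write_cluster_assignment(run$clusters, p("clusters.csv"))
  write_msp(run$spectra, p("pseudospectra.msp"))
  write_identification_table(run$ids, p("identification.csv"))
  write_compound_table(run$compound_table, p("compound_table.csv"))
  write.csv(round(run$corr_metabolites$r, 6), p("correlations.csv"))
  write_network(run$network, graphml = p("network.graphml"),
                sif = p("network.sif"))
  if (!is.null(run$trait_tables))
    write_trait_correlations(run$trait_tables, p("trait_correlations.csv"))
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# map each candidate to the true compound backing its quantification ion
candidate_truth_map <- function(run, truth) {
  setNames(truth$fragment_map$compound[
    match(run$ids$quant_fragment_id, truth$fragment_map$fragment_id)],
    run$ids$candidate_id)
}

#' Score a pipeline run against synthetic ground truth
#'
#' @param run a [run_pipeline()] result on a table rendered from `truth`
#' @param truth the [generate_truth()] object
#' @return list of scores:
#'   \describe{
#'     \item{fragment_ari}{adjusted Rand index of the recovered fragment
#'       partition against the true fragment -> compound map (contaminant
#'       fragments excluded)}
#'     \item{contaminant_recall,contaminant_precision}{planted contaminant
#'       fragments flagged / flags that are planted contaminants}
#'     \item{compound_recall,compound_precision}{true compounds whose full
#'       fragment set is recovered as one cluster / clusters that exactly
#'       match a true compound}
#'     \item{quant_rmse}{root-mean-square error of recovered log2 values
#'       against the true log2 abundance centred on the pooled-mix profile}
#'     \item{group_ari}{adjusted Rand index of the flat metabolite clusters
#'       against the planted chemical groups}
#'     \item{lactone_lipid_negative_edges}{negative network edges joining a
#'       lactone-derived and a lipid-derived candidate}
#'     \item{lactone_lipid_fraction}{those edges as a fraction of all
#'       lactone x lipid pairs present in the compound table}
#'   }
#' @export
score_against_truth <- function(run, truth) {
  run_key <- with(run$filtered$fragments, paste(fragment_id, mz, rt_s))
  truth_key <- with(truth$fragments, paste(fragment_id, mz, rt_s))
  if (!all(run_key %in% truth_key))
    stop_vocnet("run and truth do not describe the same fragments",
                "vocnet_truth_mismatch")
  flagged <- unique(c(run$contaminants$polysiloxane$flagged$fragment_id,
                      run$contaminants$blank_present$flagged$fragment_id))
  planted <- truth$contaminants$fragment_id
  contaminant_recall <- if (length(planted))
    mean(planted %in% flagged) else NA_real_
  contaminant_precision <- if (length(flagged))
    mean(flagged %in% planted) else NA_real_

  asg <- run$clusters$assignment
  true_lab <- truth$fragment_map$compound[
    match(asg$fragment_id, truth$fragment_map$fragment_id)]
  ok <- !is.na(true_lab)
  fragment_ari <- mclust::adjustedRandIndex(asg$cluster_id[ok], true_lab[ok])

  cluster_sets <- split(asg$fragment_id, asg$cluster_id)
  truth_sets <- split(truth$fragment_map$fragment_id,
                      truth$fragment_map$compound)
  canon <- function(s) paste(sort(s), collapse = "|")
  hit <- vapply(cluster_sets, canon, character(1)) %in%
    vapply(truth_sets, canon, character(1))
  compound_recall <- mean(vapply(truth_sets, canon, character(1)) %in%
                            vapply(cluster_sets, canon, character(1)))
  compound_precision <- mean(hit)

  cmap <- candidate_truth_map(run, truth)
  matched <- names(cmap)[!is.na(cmap)]
  truth_centred <- truth$abundance - log2(rowMeans(2^truth$abundance))
  vals <- run$compound_table$values[matched, , drop = FALSE]
  tv <- truth_centred[cmap[matched], colnames(vals), drop = FALSE]
  quant_rmse <- sqrt(mean((vals - tv)^2))

  grp <- setNames(truth$compounds$group, truth$compounds$name)
  cand_grp <- grp[cmap[matched]]
  group_ari <- mclust::adjustedRandIndex(
    run$hca$clusters[matched], cand_grp)

  el <- igraph::as_data_frame(run$network, what = "edges")
  gfrom <- grp[cmap[el$from]]; gto <- grp[cmap[el$to]]
  ll <- !is.na(gfrom) & !is.na(gto) &
    ((gfrom == "lactone" & gto == "lipid_derived") |
       (gfrom == "lipid_derived" & gto == "lactone"))
  ll_neg <- sum(ll & el$sign == "negative")
  n_lac <- sum(cand_grp == "lactone", na.rm = TRUE)
  n_lip <- sum(cand_grp == "lipid_derived", na.rm = TRUE)
  ll_frac <- if (n_lac * n_lip > 0) ll_neg / (n_lac * n_lip) else NA_real_

  list(fragment_ari = fragment_ari,
       contaminant_recall = contaminant_recall,
       contaminant_precision = contaminant_precision,
       compound_recall = compound_recall,
       compound_precision = compound_precision,
       quant_rmse = quant_rmse,
       group_ari = group_ari,
       lactone_lipid_negative_edges = ll_neg,
       lactone_lipid_fraction = ll_frac)
}
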