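# Metabolite-metabolite correlation analysis: HCA of compounds, thresholded
# correlation network, and ranked trait-correlation tables.

#' Number of unique unordered pairs
#'
#' @param n number of metabolites
#' @return `n * (n - 1) / 2`
#' @export
count_all_pairs <- function(n) {
  stopifnot(n >= 0)
  n * (n - 1) / 2
}

#' Metabolite-metabolite Pearson correlations
#'
#' Correlations over biological samples (the compound table holds no
#' reference or blank columns), pairwise-complete; two-sided p-values from
#' the t transform `t = r sqrt((n-2)/(1-r^2))` on `n_obs - 2` degrees of
#' freedom. Metabolites with zero variance get undefined correlations and a
#' warning; they are excluded from network construction downstream.
#'
#' @param table a [compound_table()] (log2 reference-normalized values)
#' @return object of class `correlation_matrix`: `r`, `n_obs`, `p`
#'   (symmetric matrices), `n_pairs` (unique off-diagonal pairs)
#' @export
metabolite_correlations <- function(table) {
  x <- t(table$values)
  if (nrow(x) < 3)
    stop_vocnet("need at least 3 samples for correlations",
                "vocnet_too_few_samples")
  colnames(x) <- table$compounds$candidate_id
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning(sprintf("%d metabolite(s) with zero variance: correlations undefined",
                    sum(sds == 0, na.rm = TRUE)))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(x))
  tstat <- r * sqrt(pmax(n_obs - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = pmax(n_obs - 2, 1), lower.tail = FALSE)
  diag(r) <- 1; diag(p) <- NA
  structure(list(r = r, n_obs = n_obs, p = p,
                 n_pairs = count_all_pairs(ncol(x))),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d metabolites, %d unique pairs\n",
              ncol(x$r), x$n_pairs))
  invisible(x)
}

#' Hierarchical clustering of metabolites
#'
#' Complete-linkage HCA on distance `1 - r`. Returns the tree, the leaf
#' order (for heatmap rendering) and flat clusters cut at `cut_height`
#' (default 0.4, i.e. every intra-cluster pair correlates at r >= 0.6,
#' consistent with the network cutoff).
#'
#' @param corr a `correlation_matrix`
#' @param cut_height dendrogram cut height on the `1 - r` scale
#' @return list: `tree` (hclust), `order` (leaf order), `clusters`
#'   (named integer vector of flat cluster labels)
#' @export
metabolite_hca <- function(corr, cut_height = 0.4) {
  d <- 1 - corr$r
  d[is.na(d)] <- 2
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  clusters <- stats::cutree(hc, h = cut_height)
  list(tree = hc, order = hc$labels[hc$order], clusters = clusters)
}

#' Build the thresholded correlation network
#'
#' One edge per metabolite pair with `r >= hi_cut` or `r <= lo_cut`;
#' undefined correlations never produce edges. Edges carry the correlation,
#' its sign, and a strength label following the convention that
#' `|r| >= strong_cut` is "strong" and anything between the cutoff and
#' `strong_cut` is "moderate". Nodes without any edge are dropped unless
#' `keep_isolated`.
#'
#' @param corr a `correlation_matrix`
#' @param hi_cut,lo_cut high and low correlation cutoffs
#' @param strong_cut absolute correlation above which an edge is "strong"
#' @param keep_isolated keep edge-less metabolites as isolated nodes
#' @param groups optional named vector of chemical-class labels attached to
#'   the nodes
#' @return an [igraph::graph] with edge attributes `r`, `sign`, `strength`
#'   and node attribute `group` (if supplied)
#' @export
build_network <- function(corr, hi_cut = 0.6, lo_cut = -0.6,
                          strong_cut = 0.7, keep_isolated = FALSE,
                          groups = NULL) {
  r <- corr$r
  nodes <- colnames(r)
  keep <- !lower.tri(r, diag = TRUE)
  idx <- which(keep & !is.na(r) & (r >= hi_cut | r <= lo_cut),
               arr.ind = TRUE)
  edges <- data.frame(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    r = r[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  edges$strength <- ifelse(abs(edges$r) >= strong_cut, "strong", "moderate")
  vertices <- if (keep_isolated) data.frame(name = nodes)
  else data.frame(name = sort(unique(c(edges$from, edges$to))))
  if (!is.null(groups))
    vertices$group <- unname(groups[vertices$name])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a network as GraphML and/or SIF
#'
#' Both formats load into Cytoscape. The SIF interaction type encodes the
#' edge sign (`pos`/`neg`).
#'
#' @param graph an [build_network()] result
#' @param graphml,sif output paths (either may be `NULL`)
#' @export
write_network <- function(graph, graphml = NULL, sif = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(graph, graphml, format = "graphml")
  if (!is.null(sif)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    writeLines(sprintf("%s\t%s\t%s", el$from,
                       ifelse(el$sign == "positive", "pos", "neg"), el$to),
               sif)
  }
  invisible(graph)
}

#' Trait-metabolite correlation tables
#'
#' For each quality trait, Pearson correlations against every metabolite
#' across the biological samples; the `k` strongest significant positive and
#' `k` strongest significant negative correlations are reported, sorted by
#' `|r|` within sign. p-values are raw (the selection criterion is
#' `p < alpha` without multiplicity correction); a Benjamini-Hochberg
#' adjusted column is included for reference.
#'
#' @param table a [compound_table()]
#' @param traits trait data.frame (`sample_id`, `colour_index`, `firmness`,
#'   `weight`, `ssc`); extra trait columns are picked up automatically
#' @param k entries reported per sign
#' @param alpha significance level on the raw p-value
#' @return data.frame with columns `trait`, `sign`, `metabolite`, `name`,
#'   `r`, `p`, `p_bh`
#' @export
trait_correlations <- function(table, traits, k = 9, alpha = 0.05) {
  common <- intersect(colnames(table$values), traits$sample_id)
  if (length(common) < 3)
    stop_vocnet("traits do not align with compound-table samples",
                "vocnet_too_few_samples")
  x <- t(table$values[, common, drop = FALSE])
  tr <- traits[match(common, traits$sample_id), , drop = FALSE]
  trait_names <- setdiff(names(tr), "sample_id")
  out <- list()
  for (tn in trait_names) {
    y <- tr[[tn]]
    if (all(is.na(y))) {
      warning(sprintf("trait '%s' absent for all samples; skipped", tn))
      next
    }
    n <- colSums(!is.na(x) & !is.na(y))
    r <- suppressWarnings(as.numeric(stats::cor(x, y,
                                                use = "pairwise.complete.obs")))
    tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
    p_bh <- stats::p.adjust(p, "BH")
    res <- data.frame(trait = tn, metabolite = table$compounds$candidate_id,
                      name = table$compounds$name, r = r, p = p, p_bh = p_bh,
                      stringsAsFactors = FALSE)
    res <- res[!is.na(res$r) & res$p < alpha, , drop = FALSE]
    for (sgn in c("positive", "negative")) {
      sel <- if (sgn == "positive") res[res$r > 0, ] else res[res$r < 0, ]
      sel <- sel[order(-abs(sel$r)), , drop = FALSE]
      sel <- utils::head(sel, k)
      if (nrow(sel)) {
        sel$sign <- sgn
        out[[length(out) + 1L]] <- sel
      }
    }
  }
  if (!length(out))
    return(data.frame(trait = character(0), sign = character(0),
                      metabolite = character(0), name = character(0),
                      r = numeric(0), p = numeric(0), p_bh = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("trait", "sign", "metabolite", "name", "r", "p", "p_bh")]
}

#' @rdname trait_correlations
#' @param tables result of [trait_correlations()]
#' @param path output CSV
#' @export
write_trait_correlations <- function(tables, path) {
  write.csv(tables, path, row.names = FALSE, na = "")
  invisible(path)
}
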