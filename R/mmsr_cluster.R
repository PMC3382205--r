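# Multivariate mass spectra reconstruction: fragments of one compound rise
# and fall together across samples, so cross-sample Pearson correlation plus
# a retention-time window partitions aligned fragments into candidate
# compounds.

#' Clustering parameters for mass-spectra reconstruction
#'
#' @param r_min minimum pairwise Pearson correlation within a cluster
#' @param rt_window_s maximum retention-time span (seconds) of a cluster;
#'   chosen as the maximum chromatographic peak width at half height
#' @param min_overlap minimum number of shared non-missing samples for a
#'   pairwise correlation to be defined
#' @param keep_singletons keep one-fragment clusters as low-confidence
#'   single-ion candidates (dropping them would hide genuine compounds with
#'   few fragments)
#' @return object of class `cluster_params`
#' @export
cluster_params <- function(r_min = 0.8, rt_window_s = 3, min_overlap = 10,
                           keep_singletons = TRUE) {
  stopifnot(r_min > 0, r_min < 1, rt_window_s > 0, min_overlap >= 3)
  structure(list(r_min = r_min, rt_window_s = rt_window_s,
                 min_overlap = min_overlap,
                 keep_singletons = keep_singletons),
            class = "cluster_params")
}

#' Fragment-fragment Pearson correlations
#'
#' Correlations are computed across biological and reference samples with
#' pairwise-complete observations; pairs sharing fewer than `min_overlap`
#' samples are set undefined (`NA`) so that sparsely observed fragments never
#' cluster on chance agreement.
#'
#' @param table a [fragment_table()]
#' @param params a [cluster_params()]
#' @return list with `r` (symmetric correlation matrix, unit diagonal,
#'   `NA` where undefined) and `n_obs` (pairwise overlap counts)
#' @export
fragment_correlations <- function(table, params = cluster_params()) {
  cols <- role_columns(table, c("biological", "reference"))
  x <- t(table$matrix[, cols, drop = FALSE])
  n_obs <- crossprod(!is.na(x))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[n_obs < params$min_overlap] <- NA_real_
  diag(r) <- 1
  starved <- colSums(!is.na(r)) <= 1 & nrow(x) >= params$min_overlap
  if (any(starved))
    warning(sprintf("%d fragment(s) with < %d observations on every pair",
                    sum(starved), params$min_overlap))
  list(r = r, n_obs = n_obs)
}

# split a vector of RTs (sorted order indices returned) at its largest gaps
# until every piece spans at most `window`
split_rt_span <- function(rt, window) {
  ord <- order(rt)
  pieces <- list(ord)
  repeat {
    spans <- vapply(pieces, function(ix) diff(range(rt[ix])), numeric(1))
    wide <- which(spans > window)
    if (!length(wide)) break
    i <- wide[1]
    ix <- pieces[[i]]
    gaps <- diff(rt[ix])
    cut <- which.max(gaps)
    pieces <- append(pieces[-i], list(ix[seq_len(cut)],
                                      ix[(cut + 1):length(ix)]))
  }
  pieces
}

#' Cluster fragments into candidate compounds
#'
#' Agglomerative complete-linkage clustering on distance `1 - r`, cut at
#' height `1 - r_min`; with complete linkage the cut makes the pairwise
#' `r >= r_min` rule hold for every intra-cluster pair by construction.
#' Clusters whose retention-time span exceeds `rt_window_s` are then split
#' at their largest RT gaps until all spans fit, keeping the two published
#' criteria (correlation, co-elution) independently auditable. Undefined
#' correlations are treated as distance 2 and therefore never merge.
#'
#' Fragments are ordered lexicographically by `fragment_id` before
#' clustering, so the result does not depend on input order.
#'
#' @param table a [fragment_table()]
#' @param corr result of [fragment_correlations()] on the same table
#' @param params a [cluster_params()]
#' @return object of class `fragment_clusters`: `assignment` (data.frame
#'   `fragment_id`, `cluster_id`), `clusters` (per-cluster summary:
#'   size, RT span, minimum intra-cluster r, singleton flag)
#' @export
cluster_fragments <- function(table, corr = NULL, params = cluster_params()) {
  frag <- table$fragments
  if (nrow(frag) > 0 && is.null(corr))
    corr <- fragment_correlations(table, params)
  if (nrow(frag) == 0) {
    return(structure(list(
      assignment = data.frame(fragment_id = character(0),
                              cluster_id = character(0)),
      clusters = data.frame(cluster_id = character(0), n = integer(0),
                            rt_min = numeric(0), rt_max = numeric(0),
                            rt_span = numeric(0), min_r = numeric(0),
                            singleton = logical(0)),
      params = params), class = "fragment_clusters"))
  }
  ord <- order(frag$fragment_id)   # deterministic tie-breaking
  ids <- frag$fragment_id[ord]
  rt <- frag$rt_s[ord]
  r <- corr$r[ids, ids, drop = FALSE]
  d <- 1 - r
  d[is.na(d)] <- 2                 # undefined pairs can never merge

  if (length(ids) == 1) {
    member_groups <- list(1L)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cut <- stats::cutree(hc, h = 1 - params$r_min)
    member_groups <- split(seq_along(ids), cut)
  }
  # enforce the RT window by largest-gap splitting within each r-cluster
  pieces <- list()
  for (grp in member_groups) {
    for (p in split_rt_span(rt[grp], params$rt_window_s))
      pieces[[length(pieces) + 1L]] <- grp[p]
  }
  # deterministic cluster numbering: by minimum RT, then first fragment id
  key <- order(vapply(pieces, function(ix) min(rt[ix]), numeric(1)),
               vapply(pieces, function(ix) min(ids[ix]), character(1)))
  pieces <- pieces[key]
  if (!params$keep_singletons)
    pieces <- pieces[lengths(pieces) > 1]
  cluster_id <- sprintf("C%03d", seq_along(pieces))

  assignment <- data.frame(
    fragment_id = unlist(lapply(pieces, function(ix) ids[ix])),
    cluster_id = rep(cluster_id, lengths(pieces)),
    stringsAsFactors = FALSE)
  summary <- data.frame(
    cluster_id = cluster_id,
    n = lengths(pieces),
    rt_min = vapply(pieces, function(ix) min(rt[ix]), numeric(1)),
    rt_max = vapply(pieces, function(ix) max(rt[ix]), numeric(1)),
    min_r = vapply(pieces, function(ix) {
      if (length(ix) < 2) return(NA_real_)
      min(r[ix, ix], na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  summary$rt_span <- summary$rt_max - summary$rt_min
  summary$singleton <- summary$n == 1L
  structure(list(assignment = assignment, clusters = summary,
                 params = params),
            class = "fragment_clusters")
}

#' @export
print.fragment_clusters <- function(x, ...) {
  cat(sprintf("fragment_clusters: %d clusters over %d fragments (%d singletons)\n",
              nrow(x$clusters), nrow(x$assignment), sum(x$clusters$singleton)))
  invisible(x)
}

#' Verify the clustering contract
#'
#' Checks that every intra-cluster fragment pair has a defined correlation
#' of at least `r_min` and that every cluster's retention-time span is at
#' most `rt_window_s`.
#'
#' @param clusters a `fragment_clusters` object (or any assignment
#'   data.frame with columns `fragment_id`, `cluster_id`)
#' @param corr result of [fragment_correlations()]
#' @param table the [fragment_table()] the clusters were computed on
#' @param params a [cluster_params()]
#' @return list with `ok` (logical) and `violations` (data.frame of
#'   offending pairs/clusters with the rule broken)
#' @export
verify_clusters <- function(clusters, corr, table, params = cluster_params()) {
  assignment <- if (inherits(clusters, "fragment_clusters"))
    clusters$assignment else as.data.frame(clusters)
  rt <- setNames(table$fragments$rt_s, table$fragments$fragment_id)
  violations <- list()
  for (cl in unique(assignment$cluster_id)) {
    ids <- assignment$fragment_id[assignment$cluster_id == cl]
    if (diff(range(rt[ids])) > params$rt_window_s)
      violations[[length(violations) + 1L]] <- data.frame(
        cluster_id = cl, fragment_a = NA, fragment_b = NA,
        rule = "rt_span", value = diff(range(rt[ids])))
    if (length(ids) > 1) {
      rr <- corr$r[ids, ids, drop = FALSE]
      for (i in seq_along(ids)[-length(ids)])
        for (j in (i + 1):length(ids)) {
          rij <- rr[i, j]
          if (is.na(rij) || rij < params$r_min)
            violations[[length(violations) + 1L]] <- data.frame(
              cluster_id = cl, fragment_a = ids[i], fragment_b = ids[j],
              rule = "r_min", value = rij)
        }
    }
  }
  violations <- if (length(violations)) do.call(rbind, violations)
  else data.frame(cluster_id = character(0), fragment_a = character(0),
                  fragment_b = character(0), rule = character(0),
                  value = numeric(0))
  list(ok = nrow(violations) == 0, violations = violations)
}

#' Write a cluster assignment to CSV
#'
#' @param clusters a `fragment_clusters` object
#' @param path output CSV (`fragment_id`, `cluster_id`)
#' @export
write_cluster_assignment <- function(clusters, path) {
  write.csv(clusters$assignment, path, row.names = FALSE)
  invisible(path)
}
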