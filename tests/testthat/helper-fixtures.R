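# Shared fixtures: all synthetic, built in code at test time.

# compact 2-genotype design: 16 biological + 4 reference + 2 blank over 4 days
small_design <- function(seed = 42) {
  conditions <- expand.grid(genotype = c("A", "B"), location = "L1",
                            stage = c(2L, 4L),
                            treatment = c("at_harvest", "shelf_life"),
                            stringsAsFactors = FALSE)
  conditions$n_fruits <- 2L
  design_config(conditions, n_reference = 4, n_blank = 2, n_days = 4,
                seed = seed)
}

small_truth <- function(seed = 42, sigma_log = 0.15, baseline_sd = 40,
                        n_compounds = 14, n_contaminants = 2, ...) {
  generate_truth(small_design(seed),
                 noise_config(sigma_log = sigma_log,
                              baseline_sd = baseline_sd, ...),
                 n_compounds = n_compounds,
                 n_contaminants = n_contaminants)
}

# sample metadata for hand-built tables
make_samples <- function(n_bio, n_ref = 0, n_blank = 0,
                         days_bio = 1L, days_ref = 1L, days_blank = 1L) {
  rbind(
    if (n_bio) data.frame(sample_id = sprintf("S%02d", seq_len(n_bio)),
                          role = "biological", genotype = "G", location = "L",
                          maturity_stage = 4L, treatment = "at_harvest",
                          day = rep_len(days_bio, n_bio)),
    if (n_ref) data.frame(sample_id = sprintf("R%02d", seq_len(n_ref)),
                          role = "reference", genotype = NA, location = NA,
                          maturity_stage = NA, treatment = NA,
                          day = rep_len(days_ref, n_ref)),
    if (n_blank) data.frame(sample_id = sprintf("B%02d", seq_len(n_blank)),
                            role = "blank", genotype = NA, location = NA,
                            maturity_stage = NA, treatment = NA,
                            day = rep_len(days_blank, n_blank)))
}

# rank-1 fragment table: each compound is a latent intensity series times a
# fixed fragment pattern; compounds listed as list(rt=, mz=, rel=, series=)
rank1_table <- function(compounds, n_ref = 0, n_blank = 0) {
  frag <- do.call(rbind, lapply(seq_along(compounds), function(i) {
    cmp <- compounds[[i]]
    data.frame(fragment_id = sprintf("T%d_%d", i, seq_along(cmp$mz)),
               mz = cmp$mz,
               rt_s = cmp$rt + seq(0, by = 0.2,
                                   length.out = length(cmp$mz)))
  }))
  n_smp <- length(compounds[[1]]$series)
  samples <- make_samples(n_smp, n_ref, n_blank)
  mat <- do.call(rbind, lapply(compounds, function(cmp) {
    outer(cmp$rel / max(cmp$rel), cmp$series)
  }))
  if (n_ref + n_blank > 0)
    mat <- cbind(mat, matrix(NA_real_, nrow(mat), n_ref + n_blank))
  fragment_table(frag, samples, mat)
}

# all partitions of n items as restricted-growth assignment vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, max_used) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return() }
    for (b in seq_len(max_used + 1L))
      recurse(c(assign, b), max(max_used, b))
  }
  recurse(integer(0), 0L)
  out
}

# independent brute-force edge enumeration for thresholded networks
brute_force_edges <- function(r, hi_cut, lo_cut) {
  nodes <- colnames(r)
  out <- character(0)
  for (i in seq_len(ncol(r) - 1))
    for (j in (i + 1):ncol(r)) {
      rij <- r[i, j]
      if (!is.na(rij) && (rij >= hi_cut || rij <= lo_cut))
        out <- c(out, paste(sort(c(nodes[i], nodes[j])), collapse = "--"))
    }
  sort(out)
}

edge_keys <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!nrow(el)) return(character(0))
  sort(apply(cbind(el$from, el$to), 1,
             function(x) paste(sort(x), collapse = "--")))
}
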