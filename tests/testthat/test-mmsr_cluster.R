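cp3 <- cluster_params(min_overlap = 3)

test_that("fragment correlations match the Pearson definition", {
  samples <- make_samples(4)
  frag <- data.frame(fragment_id = c("Fx", "Fy", "Fz"),
                     mz = c(43L, 57L, 71L), rt_s = c(100, 100.5, 101))
  mat <- rbind(c(1, 2, 3, 4),
               c(2, 1, 4, 3),
               3 * c(1, 2, 3, 4) + 2)
  tab <- fragment_table(frag, samples, mat)
  corr <- fragment_correlations(tab, cp3)
  expect_equal(diag(corr$r), c(Fx = 1, Fy = 1, Fz = 1))
  expect_equal(corr$r["Fx", "Fy"], 0.6)      # hand-computed Pearson r
  expect_equal(corr$r["Fx", "Fz"], 1)        # affine invariance
  expect_true(isSymmetric(corr$r))
})

test_that("pairs with insufficient overlap are undefined", {
  samples <- make_samples(12)
  frag <- data.frame(fragment_id = c("Fa", "Fb"), mz = c(43L, 57L),
                     rt_s = c(100, 100.5))
  mat <- rbind(c(1:6, rep(NA, 6)),
               c(rep(NA, 6), 1:6))   # zero shared observations
  tab <- fragment_table(frag, samples, mat)
  expect_warning(corr <- fragment_correlations(tab, cluster_params()),
                 "observations")
  expect_true(is.na(corr$r["Fa", "Fb"]))
  expect_equal(corr$n_obs["Fa", "Fb"], 0)
  # undefined pairs never merge
  cl <- cluster_fragments(tab, corr, cluster_params())
  expect_equal(nrow(cl$clusters), 2L)
})

test_that("identical profiles within the RT window form one cluster", {
  series <- c(10, 20, 15, 40, 25, 35, 5, 30)
  tab <- rank1_table(list(list(rt = 100, mz = c(43L, 57L, 71L),
                               rel = c(999, 500, 250), series = series)))
  cl <- cluster_fragments(tab, fragment_correlations(tab, cp3), cp3)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n, 3L)
})

test_that("perfect correlation cannot bridge the RT window", {
  series <- c(10, 20, 15, 40, 25, 35, 5, 30)
  tab <- rank1_table(list(
    list(rt = 100, mz = 43L, rel = 999, series = series),
    list(rt = 110, mz = 43L, rel = 999, series = series)))
  corr <- fragment_correlations(tab, cp3)
  expect_equal(corr$r[1, 2], 1)
  cl <- cluster_fragments(tab, corr, cp3)
  expect_equal(nrow(cl$clusters), 2L)          # split despite r = 1
  expect_true(all(cl$clusters$singleton))
  v <- verify_clusters(cl, corr, tab, cp3)
  expect_true(v$ok)
})

test_that("verify_clusters reports violating pairs and spans", {
  series1 <- c(10, 20, 15, 40, 25, 35, 5, 30)
  series2 <- c(30, 5, 25, 10, 40, 15, 35, 20)   # decorrelated from series1
  tab <- rank1_table(list(
    list(rt = 100, mz = c(43L, 57L), rel = c(999, 400), series = series1),
    list(rt = 300, mz = c(85L, 99L), rel = c(999, 300), series = series2)))
  corr <- fragment_correlations(tab, cp3)
  cl <- cluster_fragments(tab, corr, cp3)
  expect_true(verify_clusters(cl, corr, tab, cp3)$ok)
  merged <- cl$assignment
  merged$cluster_id <- "C001"                   # force an illegal merge
  v <- verify_clusters(merged, corr, tab, cp3)
  expect_false(v$ok)
  expect_true(any(v$violations$rule == "r_min"))
  expect_true(any(v$violations$rule == "rt_span"))
})

test_that("clustering is invariant to fragment input order", {
  truth <- small_truth(seed = 31)
  tab <- render_fragment_table(truth)$table
  cp <- cluster_params(min_overlap = 5)
  cl1 <- cluster_fragments(tab, params = cp)
  perm <- rev(seq_len(nrow(tab$fragments)))
  shuffled <- fragment_table(tab$fragments[perm, ], tab$samples,
                             tab$matrix[perm, ])
  cl2 <- cluster_fragments(shuffled, params = cp)
  part <- function(cl) unname(split(cl$assignment$fragment_id,
                                    cl$assignment$cluster_id))
  expect_setequal(vapply(part(cl1), paste, character(1), collapse = "|"),
                  vapply(part(cl2), paste, character(1), collapse = "|"))
})

test_that("raising r_min only refines the partition", {
  truth <- small_truth(seed = 33)
  tab <- render_fragment_table(truth)$table
  loose <- cluster_fragments(tab, params = cluster_params(r_min = 0.6,
                                                          min_overlap = 5))
  tight <- cluster_fragments(tab, params = cluster_params(r_min = 0.9,
                                                          min_overlap = 5))
  loose_of <- setNames(loose$assignment$cluster_id,
                       loose$assignment$fragment_id)
  # every tight cluster sits inside exactly one loose cluster
  by_tight <- split(tight$assignment$fragment_id, tight$assignment$cluster_id)
  expect_true(all(vapply(by_tight, function(ids)
    length(unique(loose_of[ids])) == 1L, logical(1))))
})

test_that("noise-free synthetic data is partitioned perfectly", {
  truth <- small_truth(seed = 35, sigma_log = 0, baseline_sd = 0)
  tab <- render_fragment_table(truth)$table
  tab <- drop_flagged(tab, flag_blank_present(tab))
  cl <- cluster_fragments(tab, params = cluster_params(min_overlap = 5))
  lab <- truth$fragment_map$compound[
    match(cl$assignment$fragment_id, truth$fragment_map$fragment_id)]
  expect_equal(mclust::adjustedRandIndex(cl$assignment$cluster_id, lab), 1)
})

test_that("empty tables yield an empty cluster set", {
  samples <- make_samples(4)
  tab <- fragment_table(
    data.frame(fragment_id = character(0), mz = integer(0),
               rt_s = numeric(0)),
    samples, matrix(numeric(0), 0, 4))
  cl <- cluster_fragments(tab, params = cp3)
  expect_equal(nrow(cl$clusters), 0L)
  expect_equal(nrow(cl$assignment), 0L)
})
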