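toy_compound_table <- function(values, ids = NULL) {
  n <- nrow(values)
  if (is.null(ids)) ids <- sprintf("C%03d", seq_len(n))
  compound_table(
    data.frame(candidate_id = ids, name = ids,
               quant_mz = 43L, rt_s = seq_len(n) * 10),
    values)
}

test_that("unique pair counts follow n(n-1)/2", {
  expect_equal(count_all_pairs(110), 5995)
  expect_equal(count_all_pairs(2), 1)
  expect_equal(count_all_pairs(1), 0)
  expect_equal(count_all_pairs(0), 0)
})

test_that("metabolite correlations are Pearson with t-transform p-values", {
  set.seed(11)
  base <- rnorm(20)
  vals <- rbind(base, base, -base, rnorm(20))
  ct <- toy_compound_table(vals)
  colnames(ct$values) <- sprintf("S%02d", 1:20)
  corr <- metabolite_correlations(ct)
  expect_equal(corr$r["C001", "C002"], 1)     # duplicated metabolite
  expect_equal(corr$r["C001", "C003"], -1)    # negation
  expect_equal(corr$n_pairs, count_all_pairs(4))
  # p-value agrees with the reference implementation
  ref <- cor.test(vals[1, ], vals[4, ])
  expect_equal(corr$p["C001", "C004"], ref$p.value)
  expect_true(isSymmetric(corr$p))
})

test_that("zero-variance metabolites are flagged and excluded from networks", {
  vals <- rbind(rnorm(10), rep(1, 10))
  ct <- toy_compound_table(vals)
  colnames(ct$values) <- sprintf("S%02d", 1:10)
  expect_warning(corr <- metabolite_correlations(ct), "zero variance")
  expect_true(is.na(corr$r["C001", "C002"]))
  g <- build_network(corr, keep_isolated = TRUE)
  expect_equal(igraph::ecount(g), 0)
})

test_that("metabolite HCA recovers block structure and merges duplicates at 0", {
  set.seed(13)
  f1 <- rnorm(30); f2 <- rnorm(30)
  vals <- rbind(f1 + rnorm(30, 0, 0.1), f1 + rnorm(30, 0, 0.1),
                f1 + rnorm(30, 0, 0.1),
                f2 + rnorm(30, 0, 0.1), f2 + rnorm(30, 0, 0.1))
  ct <- toy_compound_table(vals)
  colnames(ct$values) <- sprintf("S%02d", 1:30)
  corr <- metabolite_correlations(ct)
  hca <- metabolite_hca(corr)
  expect_equal(unname(hca$clusters), c(1, 1, 1, 2, 2))
  # members of one block are adjacent in the leaf order
  pos <- match(c("C004", "C005"), hca$order)
  expect_equal(abs(diff(pos)), 1)
  # perfectly correlated metabolites merge at height 0
  dup <- toy_compound_table(rbind(f1, 2 * f1 + 3))
  colnames(dup$values) <- sprintf("S%02d", 1:30)
  h <- metabolite_hca(metabolite_correlations(dup))
  expect_equal(h$tree$height[1], 0)
})

test_that("network construction equals brute-force thresholding", {
  set.seed(17)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(NULL, sprintf("M%d", 1:8)))
  corr <- structure(list(r = cor(x)), class = "correlation_matrix")
  g <- build_network(corr, hi_cut = 0.6, lo_cut = -0.6)
  expect_setequal(edge_keys(g), brute_force_edges(corr$r, 0.6, -0.6))
  # all-zero correlations give an empty edge set
  zero <- structure(list(r = diag(4)), class = "correlation_matrix")
  colnames(zero$r) <- rownames(zero$r) <- sprintf("M%d", 1:4)
  expect_equal(igraph::ecount(build_network(zero)), 0)
})

test_that("edge signs and strengths follow the cutoff conventions", {
  r <- diag(3)
  colnames(r) <- rownames(r) <- c("A", "B", "C")
  r["A", "B"] <- r["B", "A"] <- 0.65    # moderate positive
  r["A", "C"] <- r["C", "A"] <- -0.75   # strong negative
  g <- build_network(structure(list(r = r), class = "correlation_matrix"))
  el <- igraph::as_data_frame(g, what = "edges")
  el <- el[order(el$from, el$to), ]
  expect_equal(el$sign, c("positive", "negative"))
  expect_equal(el$strength, c("moderate", "strong"))
  expect_true(all(abs(el$r) >= 0.6))    # every edge clears a cutoff
})

test_that("raising the high cutoff never adds edges; permutation-invariant", {
  set.seed(19)
  x <- matrix(rnorm(12 * 9), 12, 9,
              dimnames = list(NULL, sprintf("M%d", 1:9)))
  corr <- structure(list(r = cor(x)), class = "correlation_matrix")
  e6 <- edge_keys(build_network(corr, hi_cut = 0.6, lo_cut = -1.01))
  e7 <- edge_keys(build_network(corr, hi_cut = 0.7, lo_cut = -1.01))
  expect_true(all(e7 %in% e6))
  perm <- sample(9)
  corr_p <- structure(list(r = corr$r[perm, perm]),
                      class = "correlation_matrix")
  expect_setequal(edge_keys(build_network(corr_p)),
                  edge_keys(build_network(corr)))
})

test_that("networks export to GraphML and SIF", {
  set.seed(23)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(NULL, sprintf("M%d", 1:6)))
  g <- build_network(structure(list(r = cor(x)),
                               class = "correlation_matrix"),
                     hi_cut = 0.3, lo_cut = -0.3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(g, graphml = gml, sif = sif)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_equal(length(readLines(sif)), igraph::ecount(g))
})

test_that("trait correlations rank significant hits by |r| within sign", {
  set.seed(29)
  n <- 40
  m1 <- rnorm(n)
  vals <- rbind(m1, -m1 + rnorm(n, 0, 0.2), rnorm(n), rnorm(n))
  ct <- toy_compound_table(vals)
  colnames(ct$values) <- sprintf("S%02d", seq_len(n))
  traits <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                       colour_index = m1)   # identical to metabolite C001
  tt <- trait_correlations(ct, traits, k = 2)
  top_pos <- tt[tt$sign == "positive", ][1, ]
  expect_equal(top_pos$metabolite, "C001")
  expect_equal(top_pos$r, 1)
  expect_true(all(tt$p < 0.05))
  neg <- tt[tt$sign == "negative", ]
  expect_equal(neg$r, neg$r[order(-abs(neg$r))])  # sorted by |r|
  # an all-missing trait is skipped with a warning
  traits$firmness <- NA_real_
  expect_warning(trait_correlations(ct, traits), "firmness")
})

test_that("an independent noise trait yields ~no strong hits", {
  set.seed(31)
  n <- 85
  vals <- matrix(rnorm(20 * n), 20, n)
  ct <- toy_compound_table(vals)
  colnames(ct$values) <- sprintf("S%02d", seq_len(n))
  hits <- replicate(200, {
    traits <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                         noise = rnorm(n))
    tt <- trait_correlations(ct, traits, alpha = 1)
    sum(abs(tt$r) >= 0.6)
  })
  expect_lt(mean(hits), 0.5)
})
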