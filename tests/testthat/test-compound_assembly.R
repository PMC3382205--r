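series_a <- c(10, 20, 15, 40, 25, 35, 5, 30)

test_that("pseudo-spectra preserve fragment intensity ratios, base 999", {
  tab <- rank1_table(list(list(rt = 100, mz = c(43L, 57L),
                               rel = c(999, 499.5), series = series_a)))
  sp <- assemble_spectrum(c("T1_1", "T1_2"), tab)
  expect_equal(unname(sp$peaks), c(999, 499.5))   # 2:1 ratio preserved
  expect_equal(sp$rt_s, median(tab$fragments$rt_s))

  single <- assemble_spectrum("T1_1", tab, candidate_id = "Cx")
  expect_equal(unname(single$peaks), 999)          # lone fragment -> base peak
  expect_equal(single$candidate_id, "Cx")
  expect_error(assemble_spectrum(character(0), tab),
               class = "vocnet_empty_cluster")
})

test_that("assembled spectra of planted compounds match their true patterns", {
  truth <- small_truth(seed = 41)
  tab <- render_fragment_table(truth)$table
  cmp <- truth$compounds$name[5]
  fids <- truth$fragment_map$fragment_id[truth$fragment_map$compound == cmp]
  sp <- assemble_spectrum(fids, tab)
  entry <- vocnet:::new_spectrum_entry(cmp, truth$patterns[[cmp]])
  m <- match_spectrum(sp, entry)
  expect_gt(m[["forward"]], 990)   # cosine >= 0.99 on the 0-1000 scale
})

test_that("quantification ions avoid co-eluting candidates", {
  tab <- rank1_table(list(
    list(rt = 100, mz = c(43L, 57L), rel = c(999, 500), series = series_a),
    list(rt = 103, mz = c(43L, 85L), rel = c(999, 400),
         series = rev(series_a))))
  sp1 <- assemble_spectrum(c("T1_1", "T1_2"), tab, "C1")
  sp2 <- assemble_spectrum(c("T2_1", "T2_2"), tab, "C2")
  expect_equal(select_quant_ion(sp1), 43L)          # alone: base peak
  # base peak m/z 43 is shared: fall through to the strongest unique ion
  expect_equal(select_quant_ion(sp1, list(sp2)), 57L)
  expect_equal(select_quant_ion(sp2, list(sp1)), 85L)
  # every ion shared -> base peak plus a warning
  sp3 <- sp2; sp3$peaks <- sp1$peaks
  expect_warning(mz <- select_quant_ion(sp3, list(sp1)), "shared")
  expect_equal(mz, 43L)
})

test_that("forward/reverse matches follow the sqrt-cosine contract", {
  q <- list(peaks = c("43" = 999, "71" = 500))
  same <- list(name = "same", peaks = c("43" = 999, "71" = 500))
  m <- match_spectrum(q, same)
  expect_equal(unname(m), c(1000, 1000))

  disjoint <- list(name = "none", peaks = c("85" = 999))
  expect_equal(match_spectrum(q, disjoint)[["forward"]], 0)

  entry <- list(name = "super", peaks = c("43" = 999, "71" = 500, "114" = 100))
  m <- match_spectrum(q, entry)
  # independent hand computation of the sqrt-intensity cosine
  qv <- sqrt(c(999, 500, 0)); ev <- sqrt(c(999, 500, 100))
  fwd <- 1000 * sum(qv * ev) / sqrt(sum(qv^2) * sum(ev^2))
  expect_equal(m[["forward"]], fwd)
  expect_lt(m[["forward"]], 1000)
  expect_equal(m[["reverse"]], 1000)   # restricted to the query's bins
})

test_that("reverse match is never below forward", {
  set.seed(7)
  for (i in 1:25) {
    qmz <- sample(35:120, sample(2:6, 1))
    emz <- unique(c(qmz, sample(35:120, sample(0:5, 1))))
    q <- list(peaks = setNames(runif(length(qmz), 1, 999), qmz))
    e <- list(name = "e", peaks = setNames(runif(length(emz), 1, 999), emz))
    m <- match_spectrum(q, e)
    expect_true(all(m >= 0 & m <= 1000))
    expect_gte(m[["reverse"]], m[["forward"]] - 1e-9)
  }
})

test_that("identification applies the threshold and containment rules", {
  tab <- rank1_table(list(
    list(rt = 100, mz = c(43L, 57L), rel = c(999, 500), series = series_a),
    list(rt = 300, mz = c(85L, 99L, 60L), rel = c(999, 500, 10),
         series = rev(series_a))))
  spectra <- list(assemble_spectrum(c("T1_1", "T1_2"), tab, "C001"),
                  assemble_spectrum(c("T2_1", "T2_2", "T2_3"), tab, "C002"))
  lib <- list(
    vocnet:::new_spectrum_entry("hexanal", c("43" = 999, "57" = 500)),
    # matches C002 well on the two big peaks but lacks its m/z 60 fragment
    vocnet:::new_spectrum_entry("limonene", c("85" = 999, "99" = 500)))
  ids <- identify_compounds(spectra, lib, match_min = 800)
  expect_true(ids$identified[ids$candidate_id == "C001"])
  expect_equal(ids$name[ids$candidate_id == "C001"], "hexanal")
  # high forward match alone is not enough: containment fails on m/z 60
  expect_gt(ids$forward_match[ids$candidate_id == "C002"], 800)
  expect_false(ids$identified[ids$candidate_id == "C002"])
  expect_equal(ids$name[ids$candidate_id == "C002"], "Ni_01")
})

test_that("unidentified candidates are numbered in retention-time order", {
  tab <- rank1_table(list(
    list(rt = 500, mz = c(43L, 57L), rel = c(999, 500), series = series_a),
    list(rt = 100, mz = c(85L, 99L), rel = c(999, 500),
         series = rev(series_a)),
    list(rt = 300, mz = c(71L, 101L), rel = c(999, 300),
         series = series_a + rev(series_a) / 3)))
  spectra <- list(assemble_spectrum(c("T1_1", "T1_2"), tab, "C001"),
                  assemble_spectrum(c("T2_1", "T2_2"), tab, "C002"),
                  assemble_spectrum(c("T3_1", "T3_2"), tab, "C003"))
  lib <- list(vocnet:::new_spectrum_entry("decoy", c("120" = 999)))
  ids <- identify_compounds(spectra, lib)
  expect_equal(ids$name[order(ids$rt_s)], c("Ni_01", "Ni_02", "Ni_03"))
  expect_equal(sum(ids$identified), 0)
})

test_that("a partial library leaves the uncovered fraction unidentified", {
  truth <- small_truth(seed = 43)
  tab <- render_fragment_table(truth)$table
  run <- run_pipeline(tab, truth_library(truth, coverage = 0.75),
                      config = pipeline_config(min_overlap = 5))
  frac_ni <- run$report$unidentified / run$report$clusters
  expect_gt(frac_ni, 0.1)
  expect_lt(frac_ni, 0.45)   # ~25% of candidates lack a library entry
})
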