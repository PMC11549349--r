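test_that("all generators are deterministic under a fixed seed", {
  expect_identical(write_newick(sim_tree(9, seed = 7)),
                   write_newick(sim_tree(9, seed = 7)))
  expect_false(identical(write_newick(sim_tree(9, seed = 7)),
                         write_newick(sim_tree(9, seed = 8))))
  phy <- sim_tree(6, seed = 1)
  expect_identical(sim_matrix(phy, 20, seed = 3)$cells,
                   sim_matrix(phy, 20, seed = 3)$cells)
  expect_identical(sim_allometric(seed = 4)$tbl_mm,
                   sim_allometric(seed = 4)$tbl_mm)
  s1 <- sim_vertebral_series(seed = 5); s2 <- sim_vertebral_series(seed = 5)
  expect_identical(s1[[7]]$lengths_mm, s2[[7]]$lengths_mm)
})

test_that("simulated trees have the requested tips", {
  for (n in c(3, 4, 10)) {
    phy <- sim_tree(n, seed = n)
    expect_equal(length(phy$tip.label), n)
    expect_true(ape::is.binary(phy))
  }
})

test_that("matrix simulation honors rate, missingness and validators", {
  phy <- sim_tree(8, seed = 2)
  # zero rate: every character constant
  m0 <- sim_matrix(phy, 30, change_rate = 0, seed = 2)
  expect_true(all(apply(m0$cells, 2, function(x) length(unique(x))) == 1))
  idx0 <- ensemble_indices(heuristic_search(m0, 2, 1, seed = 1), m0)
  expect_true(is.na(idx0["RI"]))
  # exact missing count
  m3 <- sim_matrix(phy, 50, change_rate = 0.5, missing_frac = 0.3, seed = 9)
  expect_equal(sum(m3$cells == "?"), floor(0.3 * 8 * 50))
  expect_error(sim_matrix(phy, 10, missing_frac = 1), "missing_frac")
  # output is directly consumable
  expect_s3_class(m3, "character_matrix")
  expect_silent(tree_length(phy, m3))
  # block-missing option knocks out the first half of characters
  mb <- sim_matrix(phy, 40, change_rate = 0.5, seed = 11,
                   block_missing = phy$tip.label[1:2])
  expect_true(all(mb$cells[1:2, 1:20] == "?"))
})

test_that("moderate-rate simulation lets search recover the generating tree", {
  recovered <- numeric(0)
  for (s in 1:8) {
    phy <- sim_tree(10, seed = 1000 + s)
    cm <- sim_matrix(phy, 200, k_states = 2, change_rate = 0.3,
                     seed = 2000 + s)
    r <- heuristic_search(cm, n_replicates = 3, trees_per_rep = 3,
                          seed = 3000 + s)
    recovered <- c(recovered,
                   mean(splits_of(phy, cm$taxa) %in%
                          paleosnake:::utree_splits(r$trees_ir[[1]])))
  }
  expect_gte(mean(recovered), 0.9)
})

test_that("allometric simulation hits its configured model", {
  exact <- sim_allometric(noise_sd = 0, seed = 6)
  fm <- suppressWarnings(fit_allometry(exact, "LOG10LOG10", "prW"))
  expect_equal(fm$r2, 1, tolerance = 1e-12)
  expect_equal(fm$slope, 1.0739, tolerance = 1e-9)
  noisy <- sim_allometric(n = 21, noise_sd = 0.02, seed = 7)
  fm2 <- fit_allometry(noisy, "LOG10LOG10", "prW")
  expect_lt(abs(fm2$slope - 1.0739), 0.05)
  tiny <- sim_allometric(n = 2, seed = 8)
  expect_error(fit_allometry(tiny, "LOG10LOG10"), "n >= 3")
  lin <- sim_allometric(n = 15, slope = 100.72, intercept = 436.24,
                        form = "LINEAR", noise_sd = 50, seed = 9)
  fm3 <- fit_allometry(lin, "LINEAR", "poW")
  expect_lt(abs(fm3$slope - 100.72) / 100.72, 0.1)
})

test_that("vertebral series carry the configured anatomy and ranges", {
  all_mtv <- sim_vertebral_series(atv_fraction = 0, seed = 10)
  expect_true(all(vapply(all_mtv, classify_trunk_position, "") == "MTV"))

  clean <- sim_vertebral_series(n_vertebrae = 22, atv_fraction = 0.25,
                                noise_cv = 0, seed = 12)
  cls <- vapply(clean, classify_trunk_position, "")
  expect_equal(sum(cls == "ATV"), round(0.25 * 22))
  # noise-free labels recovered from flags for every specimen
  truth <- rep(c("ATV", "MTV"), c(round(0.25 * 22), 22 - round(0.25 * 22)))
  expect_identical(unname(cls), truth)
  # configured ranges reached exactly without noise
  prw <- vapply(clean, function(s) s$lengths_mm[["prW"]], 0)
  cl <- vapply(clean, function(s) s$lengths_mm[["cL"]], 0)
  expect_equal(range(prw), c(62.4, 111.4), tolerance = 1e-9)
  expect_equal(range(cl), c(37.5, 62.7), tolerance = 1e-9)
  expect_true(all(prw / cl > 1))
})

test_that("simulated stratigraphic ranges are valid calibration input", {
  rg <- sim_strat_ranges(paste0("t", 1:12), seed = 13)
  expect_true(all(rg$fad_ma >= rg$lad_ma))
  expect_true(all(rg$lad_ma > 0))
  expect_silent(calibrate(sim_tree(12, seed = 13), rg))
})
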