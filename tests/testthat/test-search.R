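test_that("scored TBR scanning agrees with explicit neighbor construction", {
  # the search scores rearrangements by the rerooted-halves decomposition;
  # it must reproduce exactly the lengths of the fully built neighborhood
  for (s in 1:4) {
    phy <- sim_tree(7, seed = 300 + s)
    cm <- sim_matrix(phy, 15, k_states = 2 + s %% 2,
                     change_rate = 0.8, missing_frac = 0.1, seed = 400 + s)
    if (s %% 2 == 0) {
      ord <- rep(c("ORDERED", "UNORDERED"), length.out = cm$n_char)
      cm <- character_matrix(cm$taxa, cm$cells, ordering = ord)
    }
    tr <- paleosnake:::phylo_to_utree(ape::rtree(7, tip.label = cm$taxa),
                                      cm$taxa)
    sc <- paleosnake:::tbr_scan(tr, cm, keep_le = 10000L)
    expect_equal(vapply(sc$trees, function(t) tree_length(t, cm), 0L),
                 sc$lens)
    brute <- paleosnake:::tbr_neighbors(tr)
    key <- function(trees, lens) {
      sig <- vapply(trees, paleosnake:::utree_signature, "")
      tapply(lens, sig, min)
    }
    expect_equal(
      key(sc$trees, sc$lens),
      key(brute, vapply(brute, function(t) tree_length(t, cm), 0L)))
    expect_equal(sc$min_len, min(sc$lens))
  }
})

test_that("perfect data recover the generating tree with CI = 1", {
  phy <- sim_tree(10, seed = 5)
  cm <- perfect_matrix(phy, per_split = 2)
  res <- heuristic_search(cm, n_replicates = 3, trees_per_rep = 3, seed = 6)
  expect_equal(res$best_length, sum(res$per_character_min))
  expect_equal(unname(res$CI), 1.0)
  found <- paleosnake:::utree_splits(res$trees_ir[[1]])
  expect_setequal(found, splits_of(phy, cm$taxa))
})

test_that("heuristic search matches the exhaustive oracle on small matrices", {
  for (s in 1:5) {
    phy <- sim_tree(7, seed = 700 + s)
    cm <- sim_matrix(phy, 20, k_states = 2, change_rate = 1.2,
                     missing_frac = 0.1, seed = 800 + s)
    ex <- exhaustive_search(cm)
    h <- heuristic_search(cm, n_replicates = 3, trees_per_rep = 2,
                          seed = 900 + s)
    expect_equal(h$best_length, ex$best_length, info = paste("seed", s))
  }
})

test_that("search is reproducible and its pool is deduplicated", {
  phy <- sim_tree(8, seed = 44)
  cm <- sim_matrix(phy, 30, change_rate = 1.5, seed = 44)
  r1 <- heuristic_search(cm, n_replicates = 4, trees_per_rep = 4, seed = 123)
  r2 <- heuristic_search(cm, n_replicates = 4, trees_per_rep = 4, seed = 123)
  expect_identical(r1$best_length, r2$best_length)
  expect_identical(lapply(r1$trees, write_newick),
                   lapply(r2$trees, write_newick))
  sigs <- vapply(r1$trees_ir, paleosnake:::utree_signature, "")
  expect_false(any(duplicated(sigs)))
  # every retained tree sits at the reported best length
  lens <- vapply(r1$trees_ir, function(t) tree_length(t, cm), 0L)
  expect_true(all(lens == r1$best_length))
  # a different seed may legitimately differ, but must still be optimal-length
  r3 <- heuristic_search(cm, n_replicates = 4, trees_per_rep = 4, seed = 999)
  expect_equal(r3$best_length, r1$best_length)
})

test_that("search settings are validated", {
  cm <- toy_matrix(list(c("0", "0", "1", "1")))
  expect_error(heuristic_search(cm, maxtrees = 0), "maxtrees")
  small <- character_matrix(c("A", "B", "C"), matrix("0", 3, 2))
  expect_error(heuristic_search(small), "4 taxa")
})

test_that("ensemble indices match hand computations", {
  # single binary character split 2+2 scored against the incongruent tree
  # ((A,B),(C,D)): L=2, m=1, G=2 -> CI 0.5, RI 0. The search itself would
  # prefer the congruent topology, so score a fixed reference tree.
  cm <- toy_matrix(list(c("0", "1", "0", "1")))
  ref <- list(best_length = 2L,
              trees = list(read_newick("((A,B),(C,D));")))
  idx <- ensemble_indices(ref, cm)
  expect_equal(unname(idx["CI"]), 0.5)
  expect_equal(unname(idx["RI"]), 0)
  # and the search does find the 1-step topology
  res <- heuristic_search(cm, n_replicates = 2, trees_per_rep = 1, seed = 1)
  expect_equal(res$best_length, 1L)
  expect_equal(unname(res$CI), 1.0)

  # no variation at all: RI undefined, flagged not silently zero
  const <- character_matrix(c("A", "B", "C", "D"), matrix("0", 4, 3))
  res2 <- heuristic_search(const, n_replicates = 2, trees_per_rep = 1,
                           seed = 2)
  idx2 <- ensemble_indices(res2, const)
  expect_true(is.na(idx2["RI"]))
  expect_match(attr(idx2, "note"), "undefined")
})

test_that("autapomorphies shift CI only when included", {
  # char 1 congruent split, chars 2-3 autapomorphies, char 4 all-missing
  cells <- cbind(c("0", "0", "1", "1"),
                 c("1", "0", "0", "0"),
                 c("0", "0", "0", "1"),
                 c("?", "?", "?", "?"))
  cm <- character_matrix(c("A", "B", "C", "D"), cells)
  res <- heuristic_search(cm, n_replicates = 2, trees_per_rep = 1, seed = 3)
  expect_equal(res$best_length, 3L)
  all_chars <- ensemble_indices(res, cm)
  inf_only <- ensemble_indices(res, cm, informative_only = TRUE)
  expect_equal(unname(all_chars["CI"]), 1.0)   # no homoplasy anywhere
  expect_equal(unname(inf_only["CI"]), 1.0)
  # the all-missing character contributed nothing
  expect_equal(res$per_character_min[4], 0L)
  expect_equal(res$per_character_max[4], 0L)
})

test_that("Bremer decay matches an exhaustive-enumeration oracle", {
  # six taxa; (A,B) backed by 3 uncontradicted characters, (C,D) and (E,F)
  # by two each
  cells <- cbind(
    c("1", "1", "0", "0", "0", "0"), c("1", "1", "0", "0", "0", "0"),
    c("1", "1", "0", "0", "0", "0"),
    c("0", "0", "1", "1", "0", "0"), c("0", "0", "1", "1", "0", "0"),
    c("0", "0", "0", "0", "1", "1"), c("0", "0", "0", "0", "1", "1"))
  cm <- character_matrix(LETTERS[1:6], cells)
  res <- heuristic_search(cm, n_replicates = 3, trees_per_rep = 5, seed = 4)
  expect_equal(res$best_length, 7L)

  # oracle: decay per clade from all 105 topologies
  topos <- paleosnake:::all_topologies(cm$taxa)
  lens <- vapply(topos, function(t) tree_length(t, cm), 0L)
  all_splits <- lapply(topos, paleosnake:::utree_splits)
  oracle_decay <- function(sig) {
    lacking <- !vapply(all_splits, function(s) sig %in% s, TRUE)
    min(lens[lacking]) - min(lens)
  }

  brm <- bremer_support(cm, res, margin = 6, seed = 1, max_pool = 500)
  expect_true(all(brm$decay >= 0))
  # split signatures name the side away from taxon A, so the (A,B) clade
  # appears as its complement C,D,E,F
  ab_sig <- "C,D,E,F"
  ab <- brm[brm$clade == ab_sig, ]
  expect_equal(ab$decay, 3L)
  expect_equal(oracle_decay(ab_sig), 3L)
  for (i in seq_len(nrow(brm))) {
    if (!brm$at_margin[i])
      expect_equal(brm$decay[i], oracle_decay(brm$clade[i]),
                   info = brm$clade[i])
  }
  expect_error(bremer_support(cm, res, margin = -1), "margin")
})

test_that("uncontradicted clades within the margin report at the margin", {
  phy <- sim_tree(6, seed = 9)
  cm <- perfect_matrix(phy, per_split = 5)  # every clade costs 5 to break
  res <- heuristic_search(cm, n_replicates = 2, trees_per_rep = 2, seed = 10)
  brm <- bremer_support(cm, res, margin = 3, max_pool = 400)
  expect_true(all(brm$at_margin))
  expect_true(all(brm$support == ">= 3"))
})
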