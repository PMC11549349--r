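test_that("minimal four-taxon lengths match hand computation", {
  congruent <- toy_matrix(list(c("0", "0", "1", "1")))
  incongruent <- toy_matrix(list(c("0", "1", "0", "1")))
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(tree_length(tr, congruent), 1L)
  expect_equal(tree_length(tr, incongruent), 2L)
})

test_that("ordered characters pay the interval distance", {
  # states 0 vs 2 across the central edge: unordered 2 steps, ordered 4
  m <- toy_matrix(list(c("0", "2", "0", "2")))
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(tree_length(tr, m), 2L)
  m_ord <- character_matrix(m$taxa, m$cells, ordering = "ORDERED")
  expect_equal(tree_length(tr, m_ord), 4L)
  expect_equal(sankoff_length(tr, m_ord), 4L)
})

test_that("weights and inactive characters scale and drop contributions", {
  cells <- cbind(c("0", "0", "1", "1"), c("0", "1", "0", "1"))
  tr <- read_newick("((A,B),(C,D));")
  m_w <- character_matrix(c("A", "B", "C", "D"), cells, weight = c(3L, 1L))
  expect_equal(tree_length(tr, m_w), 3L + 2L)
  m_off <- character_matrix(c("A", "B", "C", "D"), cells,
                            active = c(TRUE, FALSE))
  expect_equal(tree_length(tr, m_off), 1L)
})

test_that("tree length is invariant to rooting and taxon order", {
  phy <- sim_tree(8, seed = 21)
  cm <- sim_matrix(phy, 30, k_states = 3, change_rate = 0.8,
                   missing_frac = 0.1, seed = 21)
  base <- tree_length(phy, cm)
  expect_equal(tree_length(ape::unroot(phy), cm), base)
  for (og in c(2, 5, 7)) {
    rooted <- ape::root(ape::unroot(phy), og, resolve.root = TRUE)
    expect_equal(tree_length(rooted, cm), base)
  }
  perm <- sample(seq_along(cm$taxa))
  cm_perm <- character_matrix(cm$taxa[perm], cm$cells[perm, ],
                              ordering = cm$ordering)
  expect_equal(tree_length(phy, cm_perm), base)
})

test_that("Fitch agrees with uniform-cost Sankoff across random instances", {
  for (s in 1:12) {
    phy <- sim_tree(6 + s %% 3, seed = 100 + s)
    cm <- sim_matrix(phy, 15, k_states = 2 + s %% 3,
                     change_rate = 0.5 + 0.1 * (s %% 4),
                     missing_frac = 0.1, seed = 200 + s)
    if (s %% 2 == 0) {
      ord <- rep("UNORDERED", cm$n_char)
      ord[seq(1, cm$n_char, by = 3)] <- "ORDERED"
      cm <- character_matrix(cm$taxa, cm$cells, ordering = ord)
    }
    tr <- ape::rtree(length(cm$taxa), tip.label = cm$taxa)
    expect_equal(tree_length(tr, cm), sankoff_length(tr, cm),
                 info = paste("seed", s))
  }
})

test_that("tree length matches an established parsimony implementation", {
  skip_if_not_installed("phangorn")
  phy <- sim_tree(9, seed = 31)
  cm <- sim_matrix(phy, 50, k_states = 3, change_rate = 1,
                   missing_frac = 0.2, seed = 31)
  pd <- phangorn::phyDat(
    setNames(lapply(seq_along(cm$taxa), function(i) cm$cells[i, ]), cm$taxa),
    type = "USER", levels = c("0", "1", "2"), ambiguity = "?")
  for (s in 1:5) {
    tr <- ape::rtree(9, tip.label = cm$taxa)
    expect_equal(tree_length(tr, cm),
                 as.integer(phangorn::parsimony(ape::unroot(tr), pd)))
  }
})

test_that("taxon mismatch between tree and matrix errors", {
  cm <- toy_matrix(list(c("0", "0", "1", "1")))
  tr <- read_newick("((A,B),(C,E));")
  expect_error(tree_length(tr, cm), "match")
})
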