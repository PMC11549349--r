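test_that("a toy xread parses to the expected matrix", {
  txt <- c("xread", "'toy'", "3 4",
           "A 000", "B 011", "C 101", "D 110", ";")
  cm <- read_tnt(txt)
  expect_equal(cm$taxa, c("A", "B", "C", "D"))
  expect_equal(cm$n_char, 3)
  expect_true(all(cm$ordering == "UNORDERED"))
  expect_true(all(cm$weight == 1L))
  expect_equal(unname(cm$cells[2, ]), c("0", "1", "1"))
})

test_that("polymorphism, missing and inapplicable tokens are preserved", {
  txt <- c("xread", "3 4", "A [01]?-", "B 000", "C 111", "D 0?1", ";")
  cm <- read_tnt(txt)
  expect_equal(unname(cm$cells[1, ]), c("01", "?", "-"))
  # polymorphic leaf contributes its full state set, so character 1 costs a
  # single step despite A's ambiguity; ? and - are free
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(tree_length(tr, cm, per_character = TRUE), c(1L, 1L, 1L))
})

test_that("malformed xread rows are rejected with taxon context", {
  expect_error(read_tnt(c("xread", "3 2", "A 00", "B 000", ";")), "A")
  expect_error(read_tnt(c("xread", "2 2", "A 00", "A 11", ";")), "duplicate")
  expect_error(read_tnt("nothing here"), "xread")
})

test_that("ccode statements set ordering, activity and weights", {
  txt <- c("xread", "4 4",
           "A 0000", "B 1111", "C 2222", "D 0120", ";",
           "ccode + 0 2;", "ccode ] 3;", "ccode /3 1;")
  cm <- read_tnt(txt)
  expect_equal(cm$ordering, c("ORDERED", "UNORDERED", "ORDERED", "UNORDERED"))
  expect_equal(cm$active, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cm$weight, c(1L, 3L, 1L, 1L))
})

test_that("TNT and NEXUS writers round-trip cells, ordering and activity", {
  phy <- sim_tree(6, seed = 10)
  cm <- sim_matrix(phy, 25, k_states = 3, change_rate = 0.6,
                   missing_frac = 0.15, seed = 10)
  cm$cells[2, 1] <- "02"
  cm <- character_matrix(cm$taxa, cm$cells,
                         ordering = c("ORDERED", rep("UNORDERED", 24)),
                         active = c(rep(TRUE, 24), FALSE))
  tnt <- tempfile(fileext = ".tnt"); nex <- tempfile(fileext = ".nex")
  write_tnt(cm, tnt, title = "sim")
  back <- read_tnt(tnt)
  expect_identical(back$cells, cm$cells)
  expect_identical(back$ordering, cm$ordering)
  expect_identical(back$active, cm$active)

  write_nexus(cm, nex)
  back2 <- read_nexus(nex)
  expect_identical(back2$cells, cm$cells)
})

test_that("NEXUS reader honors symbols, spaced polymorphism and guards", {
  nex <- c("#NEXUS", "BEGIN DATA;",
           "DIMENSIONS NTAX=4 NCHAR=3;",
           "FORMAT SYMBOLS=\"0 1 2\" MISSING=? GAP=-;",
           "MATRIX",
           "A (0 1)0?", "B 101", "C {12}1-", "D 000", ";", "END;")
  cm <- read_nexus(nex)
  expect_equal(unname(cm$cells[1, ]), c("01", "0", "?"))
  expect_equal(unname(cm$cells[3, ]), c("12", "1", "-"))

  bad_len <- sub("B 101", "B 10", nex)
  expect_error(read_nexus(bad_len), "NCHAR")
  bad_sym <- sub("B 101", "B 1Z1", nex)
  expect_error(read_nexus(bad_sym), "undeclared symbol")
})

test_that("matrix validation rejects malformed construction", {
  expect_error(character_matrix(c("A", "A"), matrix("0", 2, 1)), "duplicate")
  expect_error(character_matrix(c("A", "B"), matrix(c("0", "x"), 2, 1)),
               "invalid cell")
  expect_error(character_matrix(c("A", "B"), matrix("0", 2, 2),
                                outgroup = "Z"), "outgroup")
  expect_error(character_matrix(c("A", "B"), matrix("0", 2, 2),
                                weight = c(0, 1)), "weights")
})
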