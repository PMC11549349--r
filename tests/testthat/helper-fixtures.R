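# Shared fixture builders. Everything is generated in code; no files.

# a well-measured mid-trunk vertebra at the diagnosis extremes
fixture_mtv <- function(id = "MTV-1", prW = 111.4, cL = 62.7) {
  vertebra_specimen(id,
    lengths_mm = c(cL = cL, prW = prW, poW = prW * 0.95,
                   coW = 12, coH = 10, nsH = 20, tvH = 80),
    flags = c(chisel_process_present = TRUE, hemapophyses_absent = TRUE))
}

fixture_atv <- function(id = "ATV-1", prW = 70, cL = 40) {
  vertebra_specimen(id,
    lengths_mm = c(cL = cL, prW = prW),
    flags = c(hypapophysis_present = TRUE))
}

# 4-taxon toy matrices used across the parsimony tests
toy_matrix <- function(chars) {
  # chars: list of length-4 state-token vectors (A, B, C, D)
  character_matrix(c("A", "B", "C", "D"),
                   do.call(cbind, chars))
}

# a homoplasy-free matrix: every internal split of `tree` becomes
# `per_split` binary characters that change exactly once, on that edge
perfect_matrix <- function(tree, per_split = 2) {
  labels <- sort(tree$tip.label)
  splits <- paleosnake:::phylo_splits(tree, labels)
  cols <- list()
  for (sp in splits) {
    inside <- strsplit(sp, ",")[[1]]
    col <- ifelse(tree$tip.label %in% inside, "1", "0")
    for (k in seq_len(per_split)) cols[[length(cols) + 1L]] <- col
  }
  m <- do.call(cbind, cols)
  rownames(m) <- tree$tip.label
  out <- character_matrix(tree$tip.label, m)
  attr(out, "true_tree") <- tree
  out
}

splits_of <- function(tree, labels) paleosnake:::phylo_splits(tree, labels)
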