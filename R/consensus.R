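# Strict and majority-rule consensus from bipartition counts, with clade
# frequencies carried as node labels.

# splits of a phylo as canonical index signatures relative to `labels`
phylo_splits <- function(phy, labels) {
  utree_splits(phylo_to_utree(phy, labels))
}

# assemble a rooted representation of a compatible split set into Newick
clusters_to_newick <- function(labels, clusters, freq_pct) {
  n <- length(labels)
  sets <- lapply(clusters, function(s) match(strsplit(s, ",")[[1]], labels))
  sizes <- vapply(sets, length, 0L)
  ordr <- order(-sizes)
  sets <- sets[ordr]; freq_pct <- freq_pct[ordr]
  build <- function(members, avail) {
    inside <- avail[vapply(avail, function(i)
      all(sets[[i]] %in% members), TRUE)]
    # maximal clusters strictly inside `members`
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j)
        j != i && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[j]]) > length(sets[[i]]), TRUE))
    }, TRUE)]
    used <- integer(0)
    parts <- character(0)
    for (i in maximal) {
      if (any(sets[[i]] %in% used)) next  # guard; compatible sets never hit
      used <- c(used, sets[[i]])
      sub <- setdiff(inside, i)
      sub <- sub[vapply(sub, function(j)
        all(sets[[j]] %in% sets[[i]]) && length(sets[[j]]) < length(sets[[i]]),
        TRUE)]
      parts <- c(parts, paste0(build(sets[[i]], sub), freq_pct[i]))
    }
    singles <- setdiff(members, used)
    parts <- c(parts, labels[singles])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(seq_len(n), seq_along(sets)), ";")
}

# shared machinery: count splits over a tree list
count_splits <- function(trees, labels) {
  splits <- lapply(trees, function(t) {
    if (inherits(t, "utree")) utree_splits(t) else phylo_splits(t, labels)
  })
  tab <- table(unlist(splits))
  list(counts = tab, n = length(trees))
}

check_leafsets <- function(trees) {
  if (!length(trees)) stop_validation("need at least one tree")
  trees <- lapply(trees, function(t)
    if (inherits(t, "utree")) utree_to_phylo(t) else t)
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees[-1]) {
    if (!identical(sort(t$tip.label), labs))
      stop_validation("trees have different leaf sets")
  }
  list(trees = trees, labels = labs)
}

#' Strict consensus tree
#'
#' Keeps exactly the bipartitions present in every input tree.
#'
#' @param trees list of `phylo` over identical leaf sets.
#' @return a `phylo`; node labels give each retained clade's frequency
#'   (always 100 here). The split-frequency map is attached as attribute
#'   `split_freq`.
#' @export
strict_consensus <- function(trees) {
  ck <- check_leafsets(trees)
  cs <- count_splits(ck$trees, ck$labels)
  keep <- names(cs$counts)[cs$counts == cs$n]
  consensus_from_splits(ck$labels, keep,
                        rep(100, length(keep)), setNames(
                          rep(100, length(keep)), keep))
}

#' Majority-rule consensus tree
#'
#' Keeps the bipartitions occurring in strictly more than a fraction `f`
#' of the input trees (ties at exactly `f` are excluded), annotated with
#' their percentage frequency as node labels.
#'
#' @param trees list of `phylo` over identical leaf sets.
#' @param f frequency threshold in `[0.5, 1)`; default 0.5 (the standard
#'   50\% majority rule).
#' @return a `phylo` with node labels = clade frequency (percent,
#'   rounded); attribute `split_freq` maps split signatures to exact
#'   percentages.
#' @export
majority_rule <- function(trees, f = 0.5) {
  if (f < 0.5 || f >= 1) stop_validation("f must be in [0.5, 1)")
  ck <- check_leafsets(trees)
  cs <- count_splits(ck$trees, ck$labels)
  keep <- names(cs$counts)[cs$counts > f * cs$n]
  pct <- as.numeric(cs$counts[keep]) / cs$n * 100
  consensus_from_splits(ck$labels, keep, round_half_up(pct, 0),
                        setNames(pct, keep))
}

consensus_from_splits <- function(labels, splits, pct_labels, freq_map) {
  nwk <- clusters_to_newick(labels, splits, pct_labels)
  phy <- ape::read.tree(text = nwk)
  attr(phy, "split_freq") <- as.list(freq_map)
  phy
}
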