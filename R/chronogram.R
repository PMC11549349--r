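# Stratigraphically time-calibrated trees: minimum node ages from tip
# first-appearance data, with ghost-lineage bookkeeping.

#' Construct a stratigraphic range table
#'
#' @param taxon character vector.
#' @param fad_ma first appearance datum, Ma (older or equal to `lad_ma`).
#' @param lad_ma last appearance datum, Ma (> 0).
#' @return data.frame of class `strat_ranges`.
#' @export
strat_ranges <- function(taxon, fad_ma, lad_ma) {
  stopifnot(length(taxon) == length(fad_ma),
            length(fad_ma) == length(lad_ma))
  bad <- which(fad_ma < lad_ma | lad_ma <= 0)
  if (length(bad))
    stop_validation(paste0("invalid range (need fad >= lad > 0) for: ",
                           paste(taxon[bad], collapse = ", ")))
  df <- data.frame(taxon = as.character(taxon), fad_ma = fad_ma,
                   lad_ma = lad_ma, stringsAsFactors = FALSE)
  class(df) <- c("strat_ranges", "data.frame")
  df
}

#' Read a stratigraphic range CSV (`taxon,fad_ma,lad_ma`)
#' @param path CSV path.
#' @return a [strat_ranges()] table.
#' @export
read_ranges_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon", "fad_ma", "lad_ma")
  if (!all(need %in% names(df)))
    stop_validation("ranges CSV needs columns taxon,fad_ma,lad_ma")
  strat_ranges(df$taxon, df$fad_ma, df$lad_ma)
}

#' Time-calibrate a topology with stratigraphic ranges
#'
#' Minimum-age calibration: each tip is drawn at its first appearance
#' datum and each internal node at the oldest FAD among its descendants,
#' so zero-length internal edges are permitted; `root_padding` (Myr) is
#' added to the root age only. The ghost lineage of a tip is the gap
#' between its parent's age and its own FAD.
#'
#' @param tree a rooted `phylo` (root an unrooted tree on its outgroup
#'   first, e.g. via [write_newick()]'s `outgroup` or `ape::root`).
#' @param ranges a [strat_ranges()] covering every tip.
#' @param root_padding Myr added at the root (default 0).
#' @return object of class `time_tree`: list with `phylo` (edge lengths
#'   in Myr), `node_ages` (Ma, indexed like phylo nodes), `tip_ages`, and
#'   `ghost` (data.frame taxon/ghost_myr). The fad-lad bars are carried in
#'   `ranges` for rendering.
#' @export
calibrate <- function(tree, ranges, root_padding = 0) {
  stopifnot(inherits(tree, "phylo"), inherits(ranges, "strat_ranges"))
  if (root_padding < 0) stop_validation("root_padding must be >= 0")
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  miss <- setdiff(tree$tip.label, ranges$taxon)
  if (length(miss))
    stop_validation(paste0("no stratigraphic range for tip(s): ",
                           paste(miss, collapse = ", ")))
  n_tip <- length(tree$tip.label)
  fad <- ranges$fad_ma[match(tree$tip.label, ranges$taxon)]
  n_node <- tree$Nnode
  age <- c(fad, rep(NA_real_, n_node))
  tree <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    age[p] <- max(age[p], age[ch], na.rm = TRUE)
  }
  root <- n_tip + 1L
  age[root] <- age[root] + root_padding
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  parent_of_tip <- tree$edge[match(seq_len(n_tip), tree$edge[, 2]), 1]
  ghost <- data.frame(taxon = tree$tip.label,
                      ghost_myr = age[parent_of_tip] - fad,
                      stringsAsFactors = FALSE)
  structure(list(phylo = tree, node_ages = age,
                 tip_ages = setNames(fad, tree$tip.label),
                 ghost = ghost, ranges = ranges,
                 root_padding = root_padding,
                 calibration = "minimum-age (node = oldest descendant FAD)"),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("<time_tree>", length(x$phylo$tip.label), "tips;",
      x$calibration, "\n  root age:",
      max(x$node_ages), "Ma; total ghost lineage:",
      round(sum(x$ghost$ghost_myr), 2), "Myr\n")
  invisible(x)
}

#' Write a time tree as Newick (branch lengths in Myr) plus a JSON
#' node-age table
#'
#' @param tt a [calibrate()] result.
#' @param newick_path,json_path output paths (either may be `NULL`).
#' @return invisibly, a list of the written paths.
#' @export
write_time_tree <- function(tt, newick_path = NULL, json_path = NULL) {
  stopifnot(inherits(tt, "time_tree"))
  if (!is.null(newick_path)) ape::write.tree(tt$phylo, file = newick_path)
  if (!is.null(json_path)) {
    n_tip <- length(tt$phylo$tip.label)
    jsonlite::write_json(list(
      calibration = tt$calibration,
      root_padding_myr = tt$root_padding,
      node_ages_ma = tt$node_ages,
      tip_ages_ma = as.list(tt$tip_ages),
      ghost_lineages_myr = tt$ghost), json_path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(newick = newick_path, json = json_path))
}
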