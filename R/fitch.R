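# Parsimony tree length. Unordered characters use Fitch's set method on a
# bitmask encoding (vectorized across characters); ordered characters use
# the Farris interval pass; Sankoff dynamic programming with an explicit
# step-matrix is kept as an independent oracle. Missing and inapplicable
# cells are both optimized as full ambiguity over the character's observed
# states.

#' Parsimony length of a tree on a character matrix
#'
#' Sum over active characters of weight times the minimum number of state
#' changes: Fitch optimization for `UNORDERED` characters, the
#' bounded-interval (Farris) pass for `ORDERED` ones. Polymorphic cells
#' contribute their full state set at the leaf; missing (`?`) and
#' inapplicable (`-`) cells are fully ambiguous. The length is a property
#' of the unrooted topology: rooting and taxon input order do not change
#' it.
#'
#' @param tree a `phylo` (rooted or not) over exactly the matrix's taxa,
#'   or an internal `utree`.
#' @param matrix a [character_matrix()].
#' @param per_character if `TRUE`, return the per-character weighted step
#'   vector instead of the total.
#' @return integer total length (or integer vector of per-character
#'   weighted steps).
#' @export
tree_length <- function(tree, matrix, per_character = FALSE) {
  stopifnot(inherits(matrix, "character_matrix"))
  tr <- if (inherits(tree, "utree")) tree
        else phylo_to_utree(tree, matrix$taxa)
  steps <- fitch_steps(tr, matrix)
  w <- ifelse(matrix$active, matrix$weight, 0L)
  if (per_character) as.integer(steps * w) else as.integer(sum(steps * w))
}

# unweighted per-character minimum steps on a utree
fitch_steps <- function(tr, matrix) {
  mk <- matrix_masks(matrix)
  n_char <- matrix$n_char
  po <- utree_postorder(tr)
  steps <- integer(n_char)
  unord <- which(matrix$ordering == "UNORDERED")
  ord <- which(matrix$ordering == "ORDERED")

  if (length(unord)) {
    full <- mk$full[unord]
    full[full == 0L] <- 1L  # all-missing character: inert
    state <- matrix(0L, nrow = length(tr$adj), ncol = length(unord))
    add <- integer(length(unord))
    for (u in po$order) {
      if (u <= tr$n_tip) {
        m <- mk$masks[u, unord]
        m[m == 0L] <- full[m == 0L]
        state[u, ] <- m
      } else {
        kids <- tr$adj[[u]][tr$adj[[u]] != po$parent[u]]
        acc <- state[kids[1], ]
        for (k in kids[-1]) {
          b <- state[k, ]
          inter <- bitwAnd(acc, b)
          miss <- inter == 0L
          add[miss] <- add[miss] + 1L
          acc <- ifelse(miss, bitwOr(acc, b), inter)
        }
        state[u, ] <- acc
      }
    }
    steps[unord] <- add
  }

  if (length(ord)) {
    rlo <- mk$lo[ord]; rhi <- mk$hi[ord]
    lo <- matrix(0L, nrow = length(tr$adj), ncol = length(ord))
    hi <- lo
    add <- integer(length(ord))
    for (u in po$order) {
      if (u <= tr$n_tip) {
        m <- mk$masks[u, ord]
        clo <- rlo; chi <- rhi
        has <- m != 0L
        if (any(has)) {
          st <- lapply(m[has], function(mm)
            which(bitwAnd(mm, bitwShiftL(1L, 0:30)) != 0L) - 1L)
          clo[has] <- vapply(st, min, 0L)
          chi[has] <- vapply(st, max, 0L)
        }
        lo[u, ] <- clo; hi[u, ] <- chi
      } else {
        kids <- tr$adj[[u]][tr$adj[[u]] != po$parent[u]]
        alo <- lo[kids[1], ]; ahi <- hi[kids[1], ]
        for (k in kids[-1]) {
          blo <- lo[k, ]; bhi <- hi[k, ]
          nlo <- pmax(alo, blo); nhi <- pmin(ahi, bhi)
          gap <- nlo > nhi
          add[gap] <- add[gap] + (nlo - nhi)[gap]
          tmp <- nlo
          nlo[gap] <- nhi[gap]; nhi[gap] <- tmp[gap]
          alo <- nlo; ahi <- nhi
        }
        lo[u, ] <- alo; hi[u, ] <- ahi
      }
    }
    steps[ord] <- add
  }
  steps
}

#' Sankoff tree length (dynamic-programming oracle)
#'
#' Generalized parsimony by per-node state-cost vectors. With uniform
#' costs it must equal the Fitch length, and with linear costs
#' (`|i - j|`) the ordered Farris length — it is retained as an
#' independent check of the production engine, not for routine use.
#'
#' @inheritParams tree_length
#' @return integer total weighted length.
#' @export
sankoff_length <- function(tree, matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  tr <- if (inherits(tree, "utree")) tree
        else phylo_to_utree(tree, matrix$taxa)
  mk <- matrix_masks(matrix)
  po <- utree_postorder(tr)
  root <- po$order[length(po$order)]
  total <- 0
  for (j in seq_len(matrix$n_char)) {
    if (!matrix$active[j]) next
    if (mk$full[j] == 0L) next
    states <- mk$lo[j]:mk$hi[j]
    k <- length(states)
    d <- if (matrix$ordering[j] == "ORDERED")
      abs(outer(states, states, "-"))
    else
      1 - diag(k)
    cost <- matrix(0, nrow = length(tr$adj), ncol = k)
    for (u in po$order) {
      if (u <= tr$n_tip) {
        m <- mk$masks[u, j]
        allowed <- if (m == 0L) rep(TRUE, k)
                   else bitwAnd(m, bitwShiftL(1L, states)) != 0L
        cost[u, ] <- ifelse(allowed, 0, Inf)
      } else {
        kids <- tr$adj[[u]][tr$adj[[u]] != po$parent[u]]
        acc <- numeric(k)
        for (kid in kids)
          acc <- acc + apply(d + rep(cost[kid, ], each = k), 1, min)
        cost[u, ] <- acc
      }
    }
    total <- total + matrix$weight[j] * min(cost[root, ])
  }
  as.integer(total)
}

#' Exhaustive-enumeration parsimony (oracle)
#'
#' Evaluates every unrooted binary topology — (2n-5)!! trees — and returns
#' the global optimum. Usable to about 8 taxa; it is the ground truth the
#' heuristic search is tested against.
#'
#' @param matrix a [character_matrix()] with at least 4 taxa.
#' @return list with `best_length` and `trees` (list of `phylo`, all
#'   optima, deduplicated).
#' @export
exhaustive_search <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$taxa) < 4) stop_validation("need >= 4 taxa")
  topos <- all_topologies(matrix$taxa)
  lens <- vapply(topos, function(tr) tree_length(tr, matrix), 0L)
  best <- min(lens)
  keep <- topos[lens == best]
  sigs <- vapply(keep, utree_signature, "")
  keep <- keep[!duplicated(sigs)]
  list(best_length = best, trees = lapply(keep, utree_to_phylo))
}
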