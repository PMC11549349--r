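# Heuristic maximum-parsimony search: random-addition Wagner starting
# trees improved by tree-bisection-reconnection (TBR) swapping, with the
# ensemble consistency/retention indices and Bremer decay computed from
# the retained tree pool.

# --- TBR neighborhood -------------------------------------------------

# component membership after deleting edge (u, v)
utree_component <- function(adj, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (x in frontier) for (y in adj[[x]]) {
      if (!(y %in% seen)) { seen <- c(seen, y); nxt <- c(nxt, y) }
    }
    frontier <- nxt
  }
  sort(seen)
}

# All TBR rearrangements of an unrooted tree by explicit construction,
# deterministic order; includes trees identical to the input (callers
# dedupe by signature). The search itself uses the scored scan in
# tbr-engine.R; this reference implementation is retained because the two
# must agree and are cross-checked in the tests.
tbr_neighbors <- function(tr) {
  out <- list()
  ed <- utree_edges(tr)
  for (e in seq_len(nrow(ed))) {
    u <- ed[e, 1]; v <- ed[e, 2]
    adj <- tr$adj
    adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- setdiff(adj[[v]], u)
    comp1 <- utree_component(adj, u)
    comp2 <- utree_component(adj, v)
    # suppress the degree-2 vertices left by the bisection
    for (w in c(u, v)) {
      if (w > tr$n_tip && length(adj[[w]]) == 2L) {
        ab <- adj[[w]]
        adj[[ab[1]]] <- c(setdiff(adj[[ab[1]]], w), ab[2])
        adj[[ab[2]]] <- c(setdiff(adj[[ab[2]]], w), ab[1])
        adj[w] <- list(NULL)
      }
    }
    comp1 <- setdiff(comp1, c(u, v)[vapply(c(u, v), function(w)
      is.null(adj[[w]]), TRUE)])
    comp2 <- setdiff(comp2, c(u, v)[vapply(c(u, v), function(w)
      is.null(adj[[w]]), TRUE)])
    attach_points <- function(comp) {
      eds <- NULL
      for (a in comp) {
        nb <- adj[[a]]
        b <- nb[nb > a & nb %in% comp]
        if (length(b)) eds <- rbind(eds, cbind(a, sort(b)))
      }
      eds
    }
    e1 <- attach_points(comp1); e2 <- attach_points(comp2)
    for (i1 in seq_len(max(1L, NROW(e1)))) {
      for (i2 in seq_len(max(1L, NROW(e2)))) {
        adj2 <- adj
        nid <- length(adj2)
        if (is.null(e1)) p <- comp1[1]
        else {
          a <- e1[i1, 1]; b <- e1[i1, 2]
          nid <- nid + 1L; p <- nid
          adj2[[a]] <- c(setdiff(adj2[[a]], b), p)
          adj2[[b]] <- c(setdiff(adj2[[b]], a), p)
          adj2[[p]] <- c(a, b)
        }
        if (is.null(e2)) q <- comp2[1]
        else {
          a <- e2[i2, 1]; b <- e2[i2, 2]
          nid <- nid + 1L; q <- nid
          adj2[[a]] <- c(setdiff(adj2[[a]], b), q)
          adj2[[b]] <- c(setdiff(adj2[[b]], a), q)
          adj2[[q]] <- c(a, b)
        }
        adj2[[p]] <- c(adj2[[p]], q)
        adj2[[q]] <- c(adj2[[q]], p)
        out[[length(out) + 1L]] <-
          utree_compact(utree_new(tr$n_tip, tr$labels, adj2))
      }
    }
  }
  out
}

# --- heuristic search --------------------------------------------------

#' Heuristic parsimony search (random-addition Wagner trees + TBR)
#'
#' Each replicate builds a Wagner tree by greedy stepwise addition in a
#' random taxon order, then hill-climbs through TBR rearrangements,
#' accepting the first strictly shorter neighbor until none exists, and
#' finally collects up to `trees_per_rep` equally short trees from the
#' local plateau. The global pool is deduplicated by bipartition set,
#' capped at `maxtrees`, and filtered to the overall minimum length.
#' Fully reproducible: all randomness derives from `seed`.
#'
#' @param matrix a [character_matrix()] with at least 4 taxa.
#' @param n_replicates number of random-addition replicates (default 50).
#' @param trees_per_rep equally-short trees retained per replicate
#'   (default 10).
#' @param maxtrees cap on the retained tree pool (default 10000).
#' @param seed integer seed.
#' @return object of class `search_result`: list with `best_length`,
#'   `trees` (list of `phylo`), `replicate_lengths`, the per-character
#'   minimum (`per_character_min`) and maximum (`per_character_max`)
#'   conceivable steps, ensemble `CI` and `RI`, and the settings.
#' @export
heuristic_search <- function(matrix, n_replicates = 50, trees_per_rep = 10,
                             maxtrees = 10000, seed = 1) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$taxa) < 4) stop_validation("need >= 4 taxa for search")
  if (maxtrees < 1) stop_validation("maxtrees must be >= 1")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  n <- length(matrix$taxa)
  pool <- list(); pool_sigs <- character(0)
  best_len <- Inf
  rep_lens <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    ord <- sample.int(n)
    cur <- wagner_tree(matrix, ord)
    cur_len <- tree_length(cur, matrix)
    repeat {
      sc <- tbr_scan(cur, matrix, keep_le = cur_len - 1L, max_keep = 1)
      if (!length(sc$trees)) break
      cur <- sc$trees[[1]]; cur_len <- sc$lens[1]
    }
    # plateau: gather equally short trees reachable by TBR
    rep_pool <- list(cur)
    rep_sigs <- utree_signature(cur)
    frontier <- list(cur)
    while (length(frontier) && length(rep_pool) < trees_per_rep) {
      t0 <- frontier[[1]]; frontier <- frontier[-1]
      sc <- tbr_scan(t0, matrix, keep_le = cur_len,
                     max_keep = 20 * trees_per_rep)
      for (t1 in sc$trees[sc$lens == cur_len]) {
        if (length(rep_pool) >= trees_per_rep) break
        s <- utree_signature(t1)
        if (s %in% rep_sigs) next
        rep_sigs <- c(rep_sigs, s)
        rep_pool <- c(rep_pool, list(t1))
        frontier <- c(frontier, list(t1))
      }
    }
    rep_lens[r] <- cur_len
    if (cur_len < best_len) {
      best_len <- cur_len
      pool <- rep_pool; pool_sigs <- rep_sigs
    } else if (cur_len == best_len) {
      for (i in seq_along(rep_pool)) {
        if (length(pool) >= maxtrees) break
        if (!(rep_sigs[i] %in% pool_sigs)) {
          pool <- c(pool, rep_pool[i])
          pool_sigs <- c(pool_sigs, rep_sigs[i])
        }
      }
    }
  }
  if (length(pool) > maxtrees) pool <- pool[seq_len(maxtrees)]

  res <- structure(list(
    best_length = as.integer(best_len),
    trees = lapply(pool, utree_to_phylo),
    trees_ir = pool,
    replicate_lengths = rep_lens,
    n_replicates = n_replicates, trees_per_rep = trees_per_rep,
    maxtrees = maxtrees, seed = seed,
    taxa = matrix$taxa,
    per_character_min = char_min_steps(matrix),
    per_character_max = char_max_steps(matrix),
    CI = NA_real_, RI = NA_real_), class = "search_result")
  idx <- ensemble_indices(res, matrix)
  res$CI <- idx["CI"]; res$RI <- idx["RI"]
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", length(x$trees), "tree(s) at length", x$best_length,
      sprintf("\n  CI = %.3f, RI = %.3f", x$CI, x$RI),
      "\n  settings:", x$n_replicates, "replicates,",
      x$trees_per_rep, "trees/rep, seed", x$seed, "\n")
  invisible(x)
}

# minimum conceivable steps per character (weighted units applied later):
# unordered = observed states - 1; ordered = observed range
char_min_steps <- function(matrix) {
  mk <- matrix_masks(matrix)
  m <- integer(matrix$n_char)
  for (j in seq_len(matrix$n_char)) {
    if (mk$full[j] == 0L) next
    n_obs <- sum(bitwAnd(mk$full[j], bitwShiftL(1L, 0:30)) != 0L)
    m[j] <- if (matrix$ordering[j] == "ORDERED") mk$hi[j] - mk$lo[j]
            else n_obs - 1L
  }
  m
}

# maximum steps on any tree (the star-tree length): unordered =
# n_scored - max state frequency; ordered = min over a center state of
# the summed distances, polymorphic cells taking their nearest state
char_max_steps <- function(matrix) {
  mk <- matrix_masks(matrix)
  g <- integer(matrix$n_char)
  for (j in seq_len(matrix$n_char)) {
    if (mk$full[j] == 0L) next
    cells <- mk$masks[, j]
    scored <- cells != 0L
    if (!any(scored)) next
    states <- mk$lo[j]:mk$hi[j]
    if (matrix$ordering[j] == "ORDERED") {
      costs <- vapply(states, function(c0) {
        sum(vapply(cells[scored], function(m) {
          st <- which(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L) - 1L
          min(abs(st - c0))
        }, 0L))
      }, 0L)
      g[j] <- min(costs)
    } else {
      freq <- vapply(states, function(s)
        sum(bitwAnd(cells[scored], bitwShiftL(1L, s)) != 0L), 0L)
      g[j] <- sum(scored) - max(freq)
    }
  }
  g
}

#' Ensemble consistency and retention indices
#'
#' `CI = sum(w * m) / L` and `RI = (sum(w * G) - L) / (sum(w * G) -
#' sum(w * m))`, where `m` is each character's minimum conceivable steps,
#' `G` its maximum (star-tree) steps, and `L` the best tree length.
#' All-missing characters contribute zero to every sum. By default all
#' variable characters are included (autapomorphies too, the common TNT
#' report); `informative_only = TRUE` restricts every sum — including the
#' length — to parsimony-informative characters (`G > m`).
#'
#' @param result a `search_result` (or any list with `best_length` and
#'   `trees_ir`/`trees`).
#' @param matrix the [character_matrix()] that was searched.
#' @param informative_only drop parsimony-uninformative characters.
#' @return named numeric `c(CI = , RI = )`; `RI` is `NA` when the matrix
#'   has no variation beyond the minimum (`sum(G) == sum(m)`).
#' @export
ensemble_indices <- function(result, matrix, informative_only = FALSE) {
  stopifnot(inherits(matrix, "character_matrix"))
  m <- char_min_steps(matrix)
  g <- char_max_steps(matrix)
  w <- ifelse(matrix$active, matrix$weight, 0L)
  keep <- rep(TRUE, matrix$n_char)
  if (informative_only) keep <- g > m
  tr1 <- if (!is.null(result$trees_ir)) result$trees_ir[[1]]
         else result$trees[[1]]
  steps <- tree_length(tr1, matrix, per_character = TRUE)
  L <- sum(steps[keep])
  sm <- sum((w * m)[keep]); sg <- sum((w * g)[keep])
  ci <- if (L > 0) sm / L else NA_real_
  ri <- if (sg > sm) (sg - L) / (sg - sm) else NA_real_
  out <- c(CI = ci, RI = ri)
  if (sg <= sm)
    attr(out, "note") <- "RI undefined: no character varies beyond its minimum"
  out
}

# --- Bremer support ----------------------------------------------------

#' Bremer decay from a suboptimal-tree pool
#'
#' Extends the search pool by TBR-visiting trees up to
#' `best_length + margin` steps, then scores each clade of the reference
#' (majority-rule) tree by the shortest pool tree lacking it minus the
#' best length. A clade never contradicted within the margin reports
#' `">= margin"`. Because the pool is a sample of near-optimal trees, the
#' decay values are lower bounds on the true Bremer support.
#'
#' @param matrix the searched [character_matrix()].
#' @param result the `search_result`.
#' @param margin maximum suboptimality retained (default 20 steps).
#' @param seed reserved for interface stability; pool extension is
#'   deterministic.
#' @param max_pool cap on the suboptimal pool size (default 2000).
#' @return data.frame of class `bremer_table`: one row per internal clade
#'   of the reference tree, with `tips` (clade members), `frequency`
#'   (percent of best trees containing it), `decay`, `at_margin` and a
#'   printable `support` column.
#' @export
bremer_support <- function(matrix, result, margin = 20, seed = 1,
                           max_pool = 2000) {
  if (margin < 0) stop_validation("margin must be >= 0")
  best <- result$best_length
  start <- result$trees_ir %||%
    lapply(result$trees, phylo_to_utree, labels = matrix$taxa)
  pool_sigs <- vapply(start, utree_signature, "")
  pool_splits <- lapply(start, utree_splits)
  pool_lens <- rep(best, length(start))
  frontier <- start
  while (length(frontier) && length(pool_sigs) < max_pool) {
    t0 <- frontier[[1]]; frontier <- frontier[-1]
    sc <- tbr_scan(t0, matrix, keep_le = best + margin,
                   max_keep = 4 * max_pool)
    for (i in seq_along(sc$trees)) {
      if (length(pool_sigs) >= max_pool) break
      t1 <- sc$trees[[i]]
      s <- utree_signature(t1)
      if (s %in% pool_sigs) next
      pool_sigs <- c(pool_sigs, s)
      pool_splits <- c(pool_splits, list(utree_splits(t1)))
      pool_lens <- c(pool_lens, sc$lens[i])
      frontier <- c(frontier, list(t1))
    }
  }

  ref <- majority_rule(result$trees, f = 0.5)
  ref_splits <- phylo_splits(ref, matrix$taxa)
  freqs <- attr(ref, "split_freq")
  rows <- lapply(seq_along(ref_splits), function(i) {
    sp <- ref_splits[i]
    lacking <- !vapply(pool_splits, function(ps) sp %in% ps, TRUE)
    decay <- if (any(lacking)) min(pool_lens[lacking]) - best else margin
    at_margin <- !any(lacking)
    tips <- gsub(",", "+", sp)
    data.frame(clade = sp, tips = tips,
               frequency = if (!is.null(freqs)) freqs[[sp]] %||% NA_real_
                           else NA_real_,
               decay = decay, at_margin = at_margin,
               support = if (at_margin) paste0(">= ", margin)
                         else as.character(decay),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bremer_table", "data.frame")
  attr(out, "best_length") <- best
  attr(out, "margin") <- margin
  attr(out, "pool_size") <- length(pool_sigs)
  out
}
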