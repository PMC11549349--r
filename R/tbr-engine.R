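# Fast TBR scoring. Parsimony length is invariant under re-rooting, so a
# bisected tree's two halves can be scored once each, and every
# reconnection of attachment points a (in half 1) and b (in half 2) costs
#
#   L1 + L2 + join(S1[a], S2[b])
#
# where S[x] is the Fitch (or Farris-interval) state set of the half
# re-rooted on edge x, obtained for all edges at once from one postorder
# (down) and one preorder (up) pass. Candidate rearrangements are scored
# without constructing them; only accepted trees are built.

# vectorized Fitch fold over characters: sets + per-char event flags
fold_un <- function(A, B) {
  i <- bitwAnd(A, B)
  d <- i == 0L
  if (any(d)) i[d] <- bitwOr(A, B)[d]
  list(set = i, cost = d)
}

fold_ord <- function(lo1, hi1, lo2, hi2) {
  nlo <- pmax(lo1, lo2); nhi <- pmin(hi1, hi2)
  gap <- pmax(0L, nlo - nhi)
  g <- gap > 0L
  lo <- nlo; hi <- nhi
  if (any(g)) { lo[g] <- nhi[g]; hi[g] <- nlo[g] }
  list(lo = lo, hi = hi, cost = gap)
}

# leaf-level encodings with missing cells expanded to full ambiguity
leaf_info <- function(matrix) {
  mk <- matrix_masks(matrix)
  w <- ifelse(matrix$active, matrix$weight, 0L)
  unord <- which(matrix$ordering == "UNORDERED")
  ord <- which(matrix$ordering == "ORDERED")
  full <- mk$full[unord]
  full[full == 0L] <- 1L
  leaf_un <- mk$masks[, unord, drop = FALSE]
  for (i in seq_len(nrow(leaf_un))) {
    z <- leaf_un[i, ] == 0L
    if (any(z)) leaf_un[i, z] <- full[z]
  }
  n_tip <- length(matrix$taxa)
  leaf_lo <- matrix(0L, n_tip, length(ord))
  leaf_hi <- leaf_lo
  if (length(ord)) {
    for (i in seq_len(n_tip)) {
      m <- mk$masks[i, ord]
      clo <- mk$lo[ord]; chi <- mk$hi[ord]
      has <- m != 0L
      if (any(has)) {
        st <- lapply(m[has], function(mm)
          which(bitwAnd(mm, bitwShiftL(1L, 0:30)) != 0L) - 1L)
        clo[has] <- vapply(st, min, 0L)
        chi[has] <- vapply(st, max, 0L)
      }
      leaf_lo[i, ] <- clo; leaf_hi[i, ] <- chi
    }
  }
  list(unord = unord, ord = ord, w_un = w[unord], w_ord = w[ord],
       leaf_un = leaf_un, leaf_lo = leaf_lo, leaf_hi = leaf_hi,
       n_tip = n_tip)
}

# score one component: total length plus, for every edge, the state set
# of the component re-rooted on that edge (the attachment set).
# `comp` is the node set; `adj` the (already bisected/suppressed)
# adjacency. A single-tip component has one attachment: the tip itself.
component_sets <- function(adj, comp, li) {
  nu <- length(li$unord); no <- length(li$ord)
  if (length(comp) == 1L) {
    tip <- comp[1]
    return(list(
      L = 0L, n_att = 1L, attach = matrix(c(tip, NA_integer_), 1),
      S_un = li$leaf_un[tip, , drop = FALSE],
      S_lo = li$leaf_lo[tip, , drop = FALSE],
      S_hi = li$leaf_hi[tip, , drop = FALSE]))
  }
  internal <- comp[comp > li$n_tip]
  root <- if (length(internal)) internal[1] else comp[1]
  # iterative postorder within the component
  n_all <- length(adj)
  parent <- integer(n_all)
  stack <- root; parent[root] <- 0L
  visit <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, u)
    for (v in adj[[u]]) if (v != parent[u]) { parent[v] <- u; stack <- c(stack, v) }
  }
  po <- rev(visit)
  D_un <- matrix(0L, n_all, nu); D_lo <- matrix(0L, n_all, no); D_hi <- D_lo
  U_un <- matrix(0L, n_all, nu); U_lo <- matrix(0L, n_all, no); U_hi <- U_lo
  steps_un <- integer(nu); steps_ord <- integer(no)
  for (u in po) {
    if (u <= li$n_tip) {
      D_un[u, ] <- li$leaf_un[u, ]
      if (no) { D_lo[u, ] <- li$leaf_lo[u, ]; D_hi[u, ] <- li$leaf_hi[u, ] }
    } else {
      kids <- adj[[u]][adj[[u]] != parent[u]]
      au <- D_un[kids[1], ]; alo <- D_lo[kids[1], ]; ahi <- D_hi[kids[1], ]
      for (k in kids[-1]) {
        f <- fold_un(au, D_un[k, ])
        steps_un <- steps_un + f$cost
        au <- f$set
        if (no) {
          fo <- fold_ord(alo, ahi, D_lo[k, ], D_hi[k, ])
          steps_ord <- steps_ord + fo$cost
          alo <- fo$lo; ahi <- fo$hi
        }
      }
      D_un[u, ] <- au
      if (no) { D_lo[u, ] <- alo; D_hi[u, ] <- ahi }
    }
  }
  # a tip-rooted DP (2-tip component) leaves the root edge's own change
  # uncounted: add the fold against the root tip's leaf sets
  if (root <= li$n_tip && length(adj[[root]])) {
    c0 <- adj[[root]][1]
    steps_un <- steps_un + fold_un(li$leaf_un[root, ], D_un[c0, ])$cost
    if (no)
      steps_ord <- steps_ord +
        fold_ord(li$leaf_lo[root, ], li$leaf_hi[root, ],
                 D_lo[c0, ], D_hi[c0, ])$cost
  }
  L <- sum(li$w_un * steps_un) + if (no) sum(li$w_ord * steps_ord) else 0L
  # preorder: complement ("up") sets per non-root node
  for (u in visit) {          # visit is root-first
    kids <- adj[[u]][adj[[u]] != parent[u]]
    for (c0 in kids) {
      others <- kids[kids != c0]
      acc_un <- NULL; acc_lo <- NULL; acc_hi <- NULL
      if (u != root) {
        acc_un <- U_un[u, ]; acc_lo <- U_lo[u, ]; acc_hi <- U_hi[u, ]
      } else if (root <= li$n_tip) {
        # tip-rooted component: the complement of the root's only child
        # edge is the root tip itself
        acc_un <- li$leaf_un[root, ]
        acc_lo <- li$leaf_lo[root, ]; acc_hi <- li$leaf_hi[root, ]
      }
      for (s in others) {
        if (is.null(acc_un)) {
          acc_un <- D_un[s, ]; acc_lo <- D_lo[s, ]; acc_hi <- D_hi[s, ]
        } else {
          acc_un <- fold_un(acc_un, D_un[s, ])$set
          if (no) {
            fo <- fold_ord(acc_lo, acc_hi, D_lo[s, ], D_hi[s, ])
            acc_lo <- fo$lo; acc_hi <- fo$hi
          }
        }
      }
      U_un[c0, ] <- acc_un
      if (no) { U_lo[c0, ] <- acc_lo; U_hi[c0, ] <- acc_hi }
    }
  }
  # per-edge attachment sets: fold the two sides of each edge (p -> c)
  kids_of <- visit[visit != root]
  n_edge <- length(kids_of)
  S_un <- matrix(0L, n_edge, nu); S_lo <- matrix(0L, n_edge, no)
  S_hi <- S_lo
  attach <- matrix(0L, n_edge, 2)
  for (e in seq_len(n_edge)) {
    c0 <- kids_of[e]
    attach[e, ] <- c(parent[c0], c0)
    S_un[e, ] <- fold_un(D_un[c0, ], U_un[c0, ])$set
    if (no) {
      fo <- fold_ord(D_lo[c0, ], D_hi[c0, ], U_lo[c0, ], U_hi[c0, ])
      S_lo[e, ] <- fo$lo; S_hi[e, ] <- fo$hi
    }
  }
  list(L = L, n_att = n_edge, attach = attach,
       S_un = S_un, S_lo = S_lo, S_hi = S_hi)
}

# weighted join cost between attachment a of cs1 and every attachment of
# cs2 (vectorized over cs2's rows)
join_costs <- function(cs1, a, cs2, li) {
  nu <- length(li$unord); no <- length(li$ord)
  n2 <- cs2$n_att
  cost <- numeric(n2)
  if (nu) {
    A <- matrix(cs1$S_un[a, ], n2, nu, byrow = TRUE)
    disj <- bitwAnd(A, cs2$S_un) == 0L  # bitwAnd drops dim
    dim(disj) <- c(n2, nu)
    cost <- cost + as.vector(disj %*% li$w_un)
  }
  if (no) {
    lo1 <- matrix(cs1$S_lo[a, ], n2, no, byrow = TRUE)
    hi1 <- matrix(cs1$S_hi[a, ], n2, no, byrow = TRUE)
    gap <- pmax(0L, pmax(lo1, cs2$S_lo) - pmin(hi1, cs2$S_hi))
    dim(gap) <- c(n2, no)
    cost <- cost + as.vector(gap %*% li$w_ord)
  }
  cost
}

# bisect `tr` at edge (u, v); returns the suppressed adjacency and the two
# component node sets, or NULL for a degenerate bisection
bisect_tree <- function(tr, u, v) {
  adj <- tr$adj
  adj[[u]] <- setdiff(adj[[u]], v)
  adj[[v]] <- setdiff(adj[[v]], u)
  comp1 <- utree_component(adj, u)
  comp2 <- utree_component(adj, v)
  for (w in c(u, v)) {
    if (w > tr$n_tip && length(adj[[w]]) == 2L) {
      ab <- adj[[w]]
      adj[[ab[1]]] <- c(setdiff(adj[[ab[1]]], w), ab[2])
      adj[[ab[2]]] <- c(setdiff(adj[[ab[2]]], w), ab[1])
      adj[w] <- list(NULL)
      comp1 <- setdiff(comp1, w); comp2 <- setdiff(comp2, w)
    }
  }
  list(adj = adj, comp1 = comp1, comp2 = comp2)
}

# build the reconnected tree for attachment rows a (comp1) and b (comp2)
reconnect_tree <- function(tr, bi, cs1, a, cs2, b) {
  adj2 <- bi$adj
  nid <- length(adj2)
  mk_point <- function(att) {
    if (is.na(att[2])) return(att[1])  # single-tip component
    x <- att[1]; y <- att[2]
    nid <<- nid + 1L
    adj2[[x]] <<- c(setdiff(adj2[[x]], y), nid)
    adj2[[y]] <<- c(setdiff(adj2[[y]], x), nid)
    adj2[[nid]] <<- c(x, y)
    nid
  }
  p <- mk_point(cs1$attach[a, ])
  q <- mk_point(cs2$attach[b, ])
  adj2[[p]] <- c(adj2[[p]], q)
  adj2[[q]] <- c(adj2[[q]], p)
  utree_compact(utree_new(tr$n_tip, tr$labels, adj2))
}

# scan the full TBR neighborhood by scoring; construct only trees whose
# length is <= keep_le (at most max_keep of them, deterministic order).
# Returns the constructed trees, their lengths, and the minimum length
# seen anywhere in the neighborhood.
tbr_scan <- function(tr, matrix, keep_le, max_keep = Inf) {
  li <- leaf_info(matrix)
  trees <- list(); lens <- integer(0)
  min_seen <- Inf
  ed <- utree_edges(tr)
  for (e in seq_len(nrow(ed))) {
    bi <- bisect_tree(tr, ed[e, 1], ed[e, 2])
    cs1 <- component_sets(bi$adj, bi$comp1, li)
    cs2 <- component_sets(bi$adj, bi$comp2, li)
    base <- cs1$L + cs2$L
    for (a in seq_len(cs1$n_att)) {
      tot <- base + join_costs(cs1, a, cs2, li)
      m <- min(tot)
      if (m < min_seen) min_seen <- m
      keep <- which(tot <= keep_le)
      for (b in keep) {
        if (length(trees) >= max_keep) break
        nt <- reconnect_tree(tr, bi, cs1, a, cs2, b)
        trees[[length(trees) + 1L]] <- nt
        lens <- c(lens, as.integer(tot[b]))
      }
    }
  }
  list(trees = trees, lens = lens, min_len = as.integer(min_seen))
}

# greedy stepwise addition using the same scoring: inserting tip t on
# edge a costs L + join(S[a], leaf(t))
wagner_tree <- function(matrix, order) {
  n <- length(matrix$taxa)
  stopifnot(length(order) == n)
  li <- leaf_info(matrix)
  tr <- utree_star3(order[1:3], n, matrix$taxa)
  for (k in seq(4L, length.out = n - 3L)) {
    tip <- order[k]
    cs <- component_sets(tr$adj, which(!vapply(tr$adj, is.null, TRUE)), li)
    tipcs <- component_sets(tr$adj, tip, li)  # leaf sets of the new tip
    costs <- join_costs(tipcs, 1L, cs, li)
    best <- which.min(costs)
    tr <- utree_insert(tr, tip, cs$attach[best, 1], cs$attach[best, 2])
  }
  tr
}
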