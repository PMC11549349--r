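# Seeded simulators for every pipeline input: Yule topologies, Mk-style
# discrete character matrices, allometric datasets with known
# coefficients, vertebral measurement series, and stratigraphic ranges.
# These stand in for the (unbundled) supplementary measurement tables and
# character matrices, with ground truth known by construction.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Simulate a Yule (pure-birth) topology
#'
#' Grows a tree by splitting a uniformly chosen extant tip until `n_taxa`
#' tips exist — the Yule shape distribution. Branch lengths are the unit
#' depths of the splitting order (adequate for character simulation;
#' rescale as needed).
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed; identical seeds give identical trees.
#' @param labels optional tip labels (default `t1..tn`).
#' @return a rooted binary `phylo`.
#' @export
sim_tree <- function(n_taxa, seed = 1, labels = NULL) {
  stopifnot(n_taxa >= 3)
  labels <- labels %||% paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_seed(seed, {
    # children[[i]]: the two daughters of internal node i (0 = pending tip)
    tips <- list(1L, 2L)        # pending tips, by placeholder id
    nwk_id <- 2L
    # represent the growing tree as a nested list of placeholder ids
    tree <- list(1L, 2L)
    # locate and split a random pending tip by id
    split_tip <- function(node, id, a, b) {
      if (is.integer(node)) {
        if (node == id) return(list(a, b))
        return(node)
      }
      lapply(node, split_tip, id = id, a = a, b = b)
    }
    ids <- c(1L, 2L)
    while (length(ids) < n_taxa) {
      pick <- ids[sample.int(length(ids), 1L)]
      a <- nwk_id + 1L; b <- nwk_id + 2L; nwk_id <- nwk_id + 2L
      tree <- split_tip(tree, pick, a, b)
      ids <- c(setdiff(ids, pick), a, b)
    }
    perm <- sample.int(n_taxa)  # random assignment of labels to leaves
    leaf_map <- setNames(labels[perm], sort(ids))
    to_newick <- function(node) {
      if (is.integer(node)) return(paste0(leaf_map[[as.character(node)]], ":1"))
      paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), "):1")
    }
    ape::read.tree(text = paste0(to_newick(tree), ";"))
  })
}

#' Simulate a discrete morphological matrix on a known tree (Mk model)
#'
#' Each character evolves independently by a symmetric `k_states`-state
#' Markov process: the number of change events on a branch is Poisson with
#' mean `change_rate * branch_length / tree_depth`, and each event moves
#' to a uniformly chosen different state. Afterwards exactly
#' `floor(missing_frac * n_cells)` uniformly chosen cells are replaced by
#' `?`. The generating tree is attached as attribute `true_tree`.
#'
#' @param tree a rooted `phylo` with branch lengths (e.g. [sim_tree()]).
#' @param n_char number of characters.
#' @param k_states number of states (>= 2).
#' @param change_rate expected changes per character per total tree depth.
#' @param missing_frac fraction of cells knocked out, in `[0, 1)`.
#' @param seed integer seed.
#' @param block_missing optional character vector of taxa for which the
#'   first half of the characters is wholly missing — emulates
#'   vertebra-only fossil taxa unscorable for cranial characters.
#' @return a [character_matrix()] with attributes `true_tree` and `config`.
#' @export
sim_matrix <- function(tree, n_char, k_states = 2, change_rate = 1,
                       missing_frac = 0, seed = 1, block_missing = NULL) {
  stopifnot(inherits(tree, "phylo"), k_states >= 2)
  if (missing_frac < 0 || missing_frac >= 1)
    stop_validation("missing_frac must be in [0, 1)")
  taxa <- tree$tip.label
  n_tip <- length(taxa)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) depth <- 1
  with_seed(seed, {
    tr <- stats::reorder(tree, "postorder")
    # preorder traversal: root state uniform, mutate along each edge
    preord <- rev(seq_len(nrow(tr$edge)))
    cells <- matrix("?", n_tip, n_char)
    state <- matrix(0L, n_tip + tr$Nnode, n_char)
    root <- n_tip + 1L
    state[root, ] <- sample.int(k_states, n_char, replace = TRUE) - 1L
    for (e in preord) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      bl <- if (is.null(tr$edge.length)) 1 else tr$edge.length[e]
      s <- state[p, ]
      n_ev <- stats::rpois(n_char, change_rate * bl / depth)
      for (j in which(n_ev > 0)) {
        for (i in seq_len(n_ev[j])) {
          s[j] <- sample(setdiff(0:(k_states - 1L), s[j]), 1L)
        }
      }
      state[ch, ] <- s
    }
    cells[] <- as.character(state[seq_len(n_tip), ])
    if (missing_frac > 0) {
      n_miss <- floor(missing_frac * length(cells))
      idx <- sample.int(length(cells), n_miss)
      cells[idx] <- "?"
    }
    if (!is.null(block_missing)) {
      rows <- match(block_missing, taxa)
      if (anyNA(rows)) stop_validation("block_missing taxa not in tree")
      cells[rows, seq_len(floor(n_char / 2))] <- "?"
    }
    cm <- character_matrix(taxa, cells)
    attr(cm, "true_tree") <- tree
    attr(cm, "config") <- list(n_char = n_char, k_states = k_states,
                               change_rate = change_rate,
                               missing_frac = missing_frac, seed = seed)
    cm
  })
}

#' Simulate a comparative width/length dataset with known allometry
#'
#' Widths are log-uniform over `width_range_mm`; lengths follow the
#' configured model with multiplicative log-normal noise on the
#' `LOG10LOG10` scale (`noise_sd` in log10 units) or additive Gaussian
#' noise in mm for `LINEAR`.
#'
#' @param n rows (taxa); the default 21 matches the size of the extant
#'   calibration datasets the built-in equations derive from.
#' @param slope,intercept generating coefficients (defaults: the built-in
#'   log-log equation).
#' @param form `"LOG10LOG10"` (default) or `"LINEAR"`.
#' @param noise_sd noise standard deviation (log10 units or mm).
#' @param width_range_mm sampling range for widths.
#' @param seed integer seed.
#' @return a [comparative_dataset()] with attribute `config`.
#' @export
sim_allometric <- function(n = 21, slope = 1.0739, intercept = 1.9842,
                           form = c("LOG10LOG10", "LINEAR"),
                           noise_sd = 0.02, width_range_mm = c(5, 120),
                           seed = 1) {
  form <- match.arg(form)
  with_seed(seed, {
    w <- 10^stats::runif(n, log10(width_range_mm[1]), log10(width_range_mm[2]))
    tbl <- if (form == "LOG10LOG10")
      10^(slope * log10(w) + intercept + stats::rnorm(n, 0, noise_sd))
    else
      pmax(1e-6, slope * w + intercept + stats::rnorm(n, 0, noise_sd))
    ds <- comparative_dataset(sprintf("sim_taxon_%02d", seq_len(n)), w, tbl,
                              source_tag = sprintf("synthetic seed %d", seed))
    attr(ds, "config") <- list(n = n, slope = slope, intercept = intercept,
                               form = form, noise_sd = noise_sd, seed = seed)
    ds
  })
}

#' Simulate a precloacal vertebral series
#'
#' Emulates an associated precloacal column of a very large madtsoiid:
#' centrum length and prezygapophyseal width follow smooth intracolumnar
#' profiles scaled to the requested ranges (defaults: the giant-taxon
#' ranges cL 37.5-62.7 mm, prW 62.4-111.4 mm), the anterior fraction
#' carries a hypapophysis (ATV) and the remainder a chisel-shaped hemal
#' keel process (MTV), and prW/cL stays > 1 throughout.
#'
#' @param n_vertebrae series length (default 22, the confidently
#'   precloacal portion of a 27-vertebra collection).
#' @param atv_fraction fraction of anterior-trunk vertebrae in `[0, 1]`.
#' @param cl_range_mm,prw_range_mm target measurement ranges (mm).
#' @param noise_cv multiplicative measurement noise (coefficient of
#'   variation; 0 = noise-free labels).
#' @param seed integer seed.
#' @return list of [vertebra_specimen()] with attribute `config`.
#' @export
sim_vertebral_series <- function(n_vertebrae = 22, atv_fraction = 0.25,
                                 cl_range_mm = c(37.5, 62.7),
                                 prw_range_mm = c(62.4, 111.4),
                                 noise_cv = 0.02, seed = 1) {
  stopifnot(n_vertebrae >= 1, atv_fraction >= 0, atv_fraction <= 1)
  with_seed(seed, {
    pos <- seq(0, 1, length.out = n_vertebrae)  # 0 = anterior-most
    # sizes peak mid-column: scaled sine profile
    prof <- sin(pi * (0.25 + 0.75 * pos) / 1.25)
    prof <- (prof - min(prof)) / (max(prof) - min(prof))
    noise <- function(k) 1 + stats::rnorm(k, 0, noise_cv)
    cl <- (cl_range_mm[1] + prof * diff(cl_range_mm)) * noise(n_vertebrae)
    prw <- (prw_range_mm[1] + prof * diff(prw_range_mm)) * noise(n_vertebrae)
    # keep the anterior-of-posterior-trunk signature: prW/cL > 1
    prw <- pmax(prw, cl * 1.05)
    n_atv <- round(atv_fraction * n_vertebrae)
    lapply(seq_len(n_vertebrae), function(i) {
      is_atv <- i <= n_atv
      vertebra_specimen(
        specimen_id = sprintf("SYN-%03d", i),
        series_index = i,
        lengths_mm = c(cL = cl[i], prW = prw[i], poW = prw[i] * 0.92,
                       coW = cl[i] * 0.9, coH = cl[i] * 0.75,
                       nsH = cl[i] * 0.5, tvH = cl[i] * 2.0),
        angles_deg = c(alpha_syn = if (is_atv) 56.6 else 71.5,
                       beta_syn = 23),
        flags = c(hypapophysis_present = is_atv,
                  chisel_process_present = !is_atv,
                  hemapophyses_absent = TRUE,
                  sutures_closed = TRUE))
    }) -> specimens
    attr(specimens, "config") <- list(n_vertebrae = n_vertebrae,
                                      atv_fraction = atv_fraction,
                                      cl_range_mm = cl_range_mm,
                                      prw_range_mm = prw_range_mm,
                                      noise_cv = noise_cv, seed = seed)
    specimens
  })
}

#' Simulate stratigraphic ranges for a tree's tips
#'
#' Draws each tip's first appearance uniformly within `fad_window_ma` and
#' a last appearance younger by an exponential duration (capped at the
#' FAD), giving valid `fad >= lad > 0` ranges for calibration tests.
#'
#' @param taxa character vector of tip names.
#' @param fad_window_ma c(young, old) window for first appearances, Ma.
#' @param mean_duration_myr mean stratigraphic duration.
#' @param seed integer seed.
#' @return a [strat_ranges()] table.
#' @export
sim_strat_ranges <- function(taxa, fad_window_ma = c(35, 100),
                             mean_duration_myr = 5, seed = 1) {
  with_seed(seed, {
    fad <- stats::runif(length(taxa), fad_window_ma[1], fad_window_ma[2])
    dur <- pmin(stats::rexp(length(taxa), 1 / mean_duration_myr), fad - 1)
    strat_ranges(taxa, fad, pmax(fad - dur, 1))
  })
}

#' Write a vertebral series as a measurement CSV
#'
#' The same layout [read_measurements_csv()] expects; a `#`-prefixed
#' header comment records the generator configuration and seed.
#'
#' @param specimens list of [vertebra_specimen()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(specimens, path) {
  lcols <- paste0(LENGTH_FIELDS, "_mm")
  acols <- paste0(ANGLE_FIELDS, "_deg")
  rows <- lapply(specimens, function(s) {
    out <- setNames(as.list(rep(NA, 2 + length(lcols) + length(acols) +
                                  length(FLAG_FIELDS))),
                    c("specimen_id", "series_index", lcols, acols,
                      FLAG_FIELDS))
    out$specimen_id <- s$specimen_id
    out$series_index <- s$series_index
    for (nm in names(s$lengths_mm)) out[[paste0(nm, "_mm")]] <- s$lengths_mm[[nm]]
    for (nm in names(s$angles_deg)) out[[paste0(nm, "_deg")]] <- s$angles_deg[[nm]]
    for (nm in names(s$flags)) out[[nm]] <- s$flags[[nm]]
    as.data.frame(out)
  })
  df <- do.call(rbind, rows)
  cfg <- attr(specimens, "config")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(paste0("# generator config: ",
                      paste(names(cfg), unlist(lapply(cfg, paste, collapse = "/")),
                            sep = "=", collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
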