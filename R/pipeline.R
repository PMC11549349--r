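# End-to-end drivers: measurements -> trunk classification -> TBL ->
# paleotemperature, and matrix -> search -> indices -> consensus ->
# Bremer -> optional time calibration. Every number in the human-readable
# summary is also present in the returned (JSON-serializable) report.

#' Run the body-size / paleotemperature pipeline
#'
#' Classifies every vertebra, selects the mid-trunk specimens, predicts
#' total body length under each requested model, and evaluates the
#' metabolic-scaling paleotemperature at the minimum and maximum
#' estimated lengths (both equation forms).
#'
#' @param measurements either a path to a measurement CSV (see
#'   [read_measurements_csv()]) or a list of [vertebra_specimen()].
#' @param models named list of [allometric_model()] (default:
#'   [builtin_models()]). Each model uses its own `predictor` width.
#' @param temp_params a [metabolic_params()].
#' @param width_field width used for MTV selection (`"prW"` or `"poW"`).
#' @return object of class `pipeline_report` (a list): `status`
#'   (`"ok"` or `"empty"` when no MTV exists), `n_specimens`,
#'   `selected` (MTV ids in decreasing width order), `tbl` (data.frame:
#'   model, specimen, width_mm, tbl_mm, tbl_m), `tbl_range_m`, `mapt`
#'   (a [mapt_report()] at the range endpoints), `params`, `settings`.
#' @export
run_size_pipeline <- function(measurements, models = builtin_models(),
                              temp_params = metabolic_params(),
                              width_field = c("prW", "poW")) {
  width_field <- match.arg(width_field)
  specimens <- if (is.character(measurements))
    read_measurements_csv(measurements) else measurements
  mtv <- select_size_estimation_specimens(specimens, width_field)
  settings <- list(width_field = width_field,
                   models = names(models),
                   n_input = length(specimens))
  if (!length(mtv)) {
    return(structure(list(status = "empty", n_specimens = length(specimens),
                          selected = character(0), tbl = NULL,
                          tbl_range_m = NULL, mapt = NULL,
                          params = unclass(temp_params),
                          settings = settings),
                     class = "pipeline_report"))
  }
  rows <- list()
  for (mid in names(models)) {
    mod <- models[[mid]]
    for (s in mtv) {
      w <- unname(s$lengths_mm[mod$predictor])
      if (is.na(w)) next
      tbl <- predict_tbl(mod, w)
      rows[[length(rows) + 1L]] <-
        data.frame(model = mid, specimen = s$specimen_id,
                   width_mm = w, tbl_mm = unclass(tbl), tbl_m = tbl_m(tbl),
                   stringsAsFactors = FALSE)
    }
  }
  tbl_df <- do.call(rbind, rows)
  rng <- range(tbl_df$tbl_m)
  mapt_df <- mapt_report(rng, temp_params)
  structure(list(status = "ok", n_specimens = length(specimens),
                 selected = vapply(mtv, `[[`, "", "specimen_id"),
                 tbl = tbl_df, tbl_range_m = rng, mapt = mapt_df,
                 params = unclass(temp_params), settings = settings),
            class = "pipeline_report")
}

#' Run the parsimony / time-calibration pipeline
#'
#' Heuristic search with the given settings, ensemble indices,
#' 50\%-majority-rule consensus, Bremer decay from the suboptimal pool,
#' and (when ranges are supplied) a time-calibrated tree on the consensus
#' topology rooted at the matrix's outgroup.
#'
#' @param matrix a [character_matrix()], or a path to a TNT/NEXUS file
#'   (dispatched on content).
#' @param n_replicates,trees_per_rep,maxtrees,seed search settings
#'   (see [heuristic_search()]).
#' @param bremer_margin suboptimality margin for Bremer support.
#' @param ranges optional [strat_ranges()] (or CSV path) for calibration;
#'   when absent, calibration is skipped with a warning-level note in the
#'   report.
#' @param root_padding Myr added at the calibrated root.
#' @return object of class `phylo_pipeline_report`: list with `search`
#'   (a `search_result`), `consensus` (`phylo` with frequency labels),
#'   `bremer` (a `bremer_table`), `time_tree` (or `NULL`), `notes`.
#' @export
run_phylo_pipeline <- function(matrix, n_replicates = 50, trees_per_rep = 10,
                               maxtrees = 10000, seed = 1,
                               bremer_margin = 20, ranges = NULL,
                               root_padding = 0) {
  if (is.character(matrix)) {
    txt <- readLines(matrix, warn = FALSE)
    matrix <- if (any(grepl("#NEXUS", txt, ignore.case = TRUE)))
      read_nexus(txt) else read_tnt(txt)
  }
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$taxa) < 4) stop_validation("need >= 4 taxa")
  res <- heuristic_search(matrix, n_replicates, trees_per_rep, maxtrees, seed)
  cons <- majority_rule(res$trees, f = 0.5)
  brm <- bremer_support(matrix, res, margin = bremer_margin, seed = seed)
  notes <- character(0)
  tt <- NULL
  if (!is.null(ranges)) {
    if (is.character(ranges)) ranges <- read_ranges_csv(ranges)
    rooted <- if (!is.null(matrix$outgroup))
      ape::root(cons, outgroup = matrix$outgroup, resolve.root = TRUE)
    else ape::root(cons, 1, resolve.root = TRUE)
    tt <- calibrate(rooted, ranges, root_padding = root_padding)
  } else {
    notes <- c(notes, "no stratigraphic ranges supplied; calibration skipped")
  }
  structure(list(search = res, consensus = cons, bremer = brm,
                 time_tree = tt, notes = notes,
                 settings = list(n_replicates = n_replicates,
                                 trees_per_rep = trees_per_rep,
                                 maxtrees = maxtrees, seed = seed,
                                 bremer_margin = bremer_margin,
                                 root_padding = root_padding)),
            class = "phylo_pipeline_report")
}

#' Write a pipeline report as JSON
#' @param report a `pipeline_report` or `phylo_pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ser <- serialize_report(report)
  jsonlite::write_json(ser, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

serialize_report <- function(report) {
  if (inherits(report, "phylo_pipeline_report")) {
    res <- report$search
    list(settings = report$settings,
         best_length = res$best_length,
         n_best_trees = length(res$trees),
         CI = unname(res$CI), RI = unname(res$RI),
         replicate_lengths = res$replicate_lengths,
         consensus_newick = write_newick(report$consensus),
         bremer = as.data.frame(report$bremer),
         time_tree_newick = if (!is.null(report$time_tree))
           write_newick(report$time_tree$phylo) else NULL,
         notes = report$notes)
  } else {
    unclass(report)
  }
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> status:", x$status, "\n")
  if (x$status == "empty") {
    cat("  no mid-trunk specimens among", x$n_specimens, "input vertebrae\n")
    return(invisible(x))
  }
  cat("  MTV selected:", paste(x$selected, collapse = ", "), "\n")
  agg <- stats::aggregate(tbl_m ~ model, data = x$tbl, FUN = range)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: TBL %.1f-%.1f m\n", agg$model[i],
                agg$tbl_m[i, 1], agg$tbl_m[i, 2]))
  cat(sprintf("  MAPT (exact form) at %.1f-%.1f m: %.1f-%.1f degC\n",
              x$tbl_range_m[1], x$tbl_range_m[2],
              round_half_up(min(x$mapt$mapt_exact_c), 1),
              round_half_up(max(x$mapt$mapt_exact_c), 1)))
  invisible(x)
}
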