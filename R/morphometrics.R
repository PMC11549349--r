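# Vertebral morphometrics: measurement containers, the ratio suite used in
# madtsoiid descriptions, and trunk-position classification of precloacal
# vertebrae.

# fixed measurement vocabulary (all mm)
LENGTH_FIELDS <- c("cL", "prW", "poW", "coW", "coH", "cnW", "cnH", "ncW",
                   "ncH", "zsW", "zsH", "zsfL", "zsfW", "przL", "przW",
                   "pozL", "pozW", "nsH", "tvH")
# angles (degrees)
ANGLE_FIELDS <- c("alpha_syn", "beta_syn", "pr_alpha", "po_alpha",
                  "zs_alpha", "ns_incl")
FLAG_FIELDS <- c("hypapophysis_present", "chisel_process_present",
                 "hemapophyses_absent", "sutures_closed")
POSITION_CLASSES <- c("ATV", "MTV", "POSTERIOR_TRUNK", "CLOACAL_CAUDAL",
                      "UNKNOWN")

# numerator/denominator pairs of the reported ratio suite
RATIO_DEFS <- list(
  "coW/coH"   = c("coW", "coH"),
  "cnW/cnH"   = c("cnW", "cnH"),
  "ncW/ncH"   = c("ncW", "ncH"),
  "zsW/zsH"   = c("zsW", "zsH"),
  "zsfL/zsfW" = c("zsfL", "zsfW"),
  "przL/przW" = c("przL", "przW"),
  "pozL/pozW" = c("pozL", "pozW"),
  "nsH/tvH"   = c("nsH", "tvH"),
  "prW/cL"    = c("prW", "cL"),
  "poW/cL"    = c("poW", "cL")
)

#' Construct a vertebra specimen record
#'
#' Holds one vertebra's linear measurements (mm), angles (degrees),
#' anatomical flags and (optionally) its inferred position along the
#' precloacal column. Missing measurements are simply omitted; they are
#' never coded as zero.
#'
#' @param specimen_id character scalar, collection number.
#' @param lengths_mm named numeric vector; names from the fixed vocabulary
#'   `cL, prW, poW, coW, coH, cnW, cnH, ncW, ncH, zsW, zsH, zsfL, zsfW,
#'   przL, przW, pozL, pozW, nsH, tvH`. All values must be > 0.
#' @param angles_deg named numeric vector; names from `alpha_syn, beta_syn,
#'   pr_alpha, po_alpha, zs_alpha, ns_incl`; values in (0, 180].
#' @param flags named logical vector; names from `hypapophysis_present,
#'   chisel_process_present, hemapophyses_absent, sutures_closed`.
#' @param series_index optional integer: position within an articulated
#'   specimen (the Roman numerals of multi-vertebra blocks).
#' @param position_class one of `ATV`, `MTV`, `POSTERIOR_TRUNK`,
#'   `CLOACAL_CAUDAL`, `UNKNOWN` (default).
#' @return an object of class `vertebra_specimen`.
#' @export
vertebra_specimen <- function(specimen_id, lengths_mm = numeric(),
                              angles_deg = numeric(), flags = logical(),
                              series_index = NA_integer_,
                              position_class = "UNKNOWN") {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  lengths_mm <- unlist(lengths_mm)
  angles_deg <- unlist(angles_deg)
  flags <- unlist(flags)
  if (length(lengths_mm)) {
    bad <- setdiff(names(lengths_mm), LENGTH_FIELDS)
    if (length(bad)) stop_validation(paste0("unknown length field(s): ",
                                            paste(bad, collapse = ", ")))
    np <- names(lengths_mm)[!is.na(lengths_mm) & lengths_mm <= 0]
    if (length(np)) stop_validation(paste0("non-positive length in field(s): ",
                                           paste(np, collapse = ", ")))
    lengths_mm <- lengths_mm[!is.na(lengths_mm)]
  }
  if (length(angles_deg)) {
    bad <- setdiff(names(angles_deg), ANGLE_FIELDS)
    if (length(bad)) stop_validation(paste0("unknown angle field(s): ",
                                            paste(bad, collapse = ", ")))
    out <- names(angles_deg)[!is.na(angles_deg) &
                             (angles_deg <= 0 | angles_deg > 180)]
    if (length(out)) stop_validation(paste0("angle outside (0, 180] in: ",
                                            paste(out, collapse = ", ")))
    angles_deg <- angles_deg[!is.na(angles_deg)]
  }
  if (length(flags)) {
    bad <- setdiff(names(flags), FLAG_FIELDS)
    if (length(bad)) stop_validation(paste0("unknown flag(s): ",
                                            paste(bad, collapse = ", ")))
  }
  position_class <- match.arg(position_class, POSITION_CLASSES)
  structure(list(specimen_id = specimen_id,
                 series_index = as.integer(series_index),
                 lengths_mm = lengths_mm,
                 angles_deg = angles_deg,
                 flags = flags,
                 position_class = position_class),
            class = "vertebra_specimen")
}

#' @export
print.vertebra_specimen <- function(x, ...) {
  cat("<vertebra_specimen>", x$specimen_id,
      if (!is.na(x$series_index)) paste0("(series ", x$series_index, ")"),
      "\n  position:", x$position_class,
      "\n  lengths recorded:", length(x$lengths_mm),
      " angles recorded:", length(x$angles_deg), "\n")
  invisible(x)
}

#' Compute the vertebral ratio suite
#'
#' Evaluates the fixed set of descriptive ratios (cotyle, condyle, neural
#' canal, zygosphene, facet proportions, neural-spine height fraction and
#' the two width-to-centrum-length indices) for a single specimen. A ratio
#' is computed only when both operands were measured; otherwise it is
#' listed under `missing`. Stored measurements are never modified: rounding
#' applies to the report only.
#'
#' @param specimen a [vertebra_specimen()].
#' @param decimals integer >= 0; reported ratios are rounded half-up to
#'   this many decimals (descriptions typically print 1-2).
#' @return an object of class `ratio_report`: list with `specimen_id`,
#'   `ratios` (named numeric) and `missing` (character).
#' @examples
#' v <- vertebra_specimen("X-1", lengths_mm = c(coW = 12, coH = 10))
#' compute_ratio_suite(v, decimals = 1)$ratios  # coW/coH = 1.2
#' @export
compute_ratio_suite <- function(specimen, decimals = 2) {
  stopifnot(inherits(specimen, "vertebra_specimen"))
  if (!length(specimen$lengths_mm))
    stop_validation("specimen has no recorded lengths")
  if (decimals < 0) stop_validation("decimals must be >= 0")
  L <- specimen$lengths_mm
  ratios <- numeric(0)
  missing <- character(0)
  for (nm in names(RATIO_DEFS)) {
    ops <- RATIO_DEFS[[nm]]
    if (all(ops %in% names(L))) {
      ratios[nm] <- round_half_up(L[[ops[1]]] / L[[ops[2]]], decimals)
    } else {
      missing <- c(missing, nm)
    }
  }
  structure(list(specimen_id = specimen$specimen_id,
                 ratios = ratios, missing = missing),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat("<ratio_report>", x$specimen_id, "\n")
  if (length(x$ratios))
    print(x$ratios)
  if (length(x$missing))
    cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a precloacal vertebra by trunk position
#'
#' Applies the standard positional criteria for snake precloacal vertebrae:
#' a hypapophysis marks the anterior trunk (ATV); a chisel-shaped posterior
#' process of the hemal keel marks the mid-trunk (MTV); failing anatomical
#' flags, a neural-arch width exceeding the centrum length (width/cL > 1)
#' places the vertebra anterior to the posterior trunk and is read as MTV,
#' while width/cL <= 1 is labelled POSTERIOR_TRUNK. Scope is precloacal
#' only: CLOACAL_CAUDAL is never returned.
#'
#' @param specimen a [vertebra_specimen()].
#' @param width_field which width to use for the metric rule: `"prW"`
#'   (default) or `"poW"`.
#' @return a single position class string; `"UNKNOWN"` when neither
#'   measurements nor flags are available.
#' @export
classify_trunk_position <- function(specimen, width_field = c("prW", "poW")) {
  stopifnot(inherits(specimen, "vertebra_specimen"))
  width_field <- match.arg(width_field)
  fl <- specimen$flags
  if (isTRUE(unname(fl["hypapophysis_present"]))) return("ATV")
  if (isTRUE(unname(fl["chisel_process_present"]))) return("MTV")
  L <- specimen$lengths_mm
  if (all(c("cL", width_field) %in% names(L))) {
    if (L[[width_field]] / L[["cL"]] > 1) return("MTV")
    return("POSTERIOR_TRUNK")
  }
  "UNKNOWN"
}

#' Select the specimens used for body-size estimation
#'
#' Size estimates are made from mid-trunk vertebrae, the largest elements
#' of the precloacal series. Returns the MTV subset sorted by decreasing
#' width (ties broken by specimen id).
#'
#' @param collection list of [vertebra_specimen()].
#' @param width_field `"prW"` or `"poW"`; used both for classification and
#'   for the sort key.
#' @return list of `vertebra_specimen`, possibly empty. Specimens whose
#'   chosen width is unrecorded sort last among the MTV.
#' @export
select_size_estimation_specimens <- function(collection,
                                             width_field = c("prW", "poW")) {
  width_field <- match.arg(width_field)
  if (!length(collection)) stop_validation("collection is empty")
  cls <- vapply(collection, classify_trunk_position, "",
                width_field = width_field)
  mtv <- collection[cls == "MTV"]
  if (!length(mtv)) return(list())
  w <- vapply(mtv, function(s) {
    v <- unname(s$lengths_mm[width_field])
    if (is.na(v)) -Inf else v
  }, 0)
  ids <- vapply(mtv, `[[`, "", "specimen_id")
  mtv[order(-w, ids)]
}

#' Read a vertebral measurement table
#'
#' One row per vertebra. Expected columns: `specimen_id`, optional
#' `series_index`, lengths as `<name>_mm`, angles as `<name>_deg`, flags by
#' their bare names (logical or 0/1). Empty cells are missing measurements.
#'
#' @param path CSV file path (UTF-8, header mandatory).
#' @return list of [vertebra_specimen()].
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#", fileEncoding = "UTF-8")
  if (!"specimen_id" %in% names(df))
    stop_validation("measurement CSV must have a specimen_id column")
  lcols <- paste0(LENGTH_FIELDS, "_mm")
  acols <- paste0(ANGLE_FIELDS, "_deg")
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    take <- function(cols, strip) {
      present <- intersect(cols, names(df))
      v <- as.numeric(row[1, present])
      names(v) <- sub(strip, "", present)
      v[!is.na(v)]
    }
    fl <- intersect(FLAG_FIELDS, names(df))
    flags <- as.logical(unlist(row[1, fl]))
    names(flags) <- fl
    flags <- flags[!is.na(flags)]
    vertebra_specimen(
      specimen_id = as.character(row$specimen_id),
      series_index = if ("series_index" %in% names(df))
        as.integer(row$series_index) else NA_integer_,
      lengths_mm = take(lcols, "_mm$"),
      angles_deg = take(acols, "_deg$"),
      flags = flags)
  })
}

#' Serialize ratio reports
#'
#' Writes one or many ratio reports to CSV (one row per specimen, one
#' column per ratio, `NA` where operands were missing) or to JSON with
#' identical content.
#'
#' @param reports a `ratio_report` or list of them.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_ratio_reports <- function(reports, path) {
  if (inherits(reports, "ratio_report")) reports <- list(reports)
  all_names <- names(RATIO_DEFS)
  rows <- lapply(reports, function(r) {
    v <- setNames(rep(NA_real_, length(all_names)), all_names)
    v[names(r$ratios)] <- r$ratios
    c(list(specimen_id = r$specimen_id), as.list(v))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
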