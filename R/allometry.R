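# Total-body-length allometry on zygapophyseal widths: built-in predictive
# equations, OLS fitting, inverse prediction, prediction intervals.

#' Construct an allometric total-body-length model
#'
#' A TBL-on-width regression in one of two forms. `LINEAR` predicts
#' `tbl_mm = slope * width_mm + intercept`; `LOG10LOG10` predicts
#' `log10(tbl_mm) = slope * log10(width_mm) + intercept`. Both operate in
#' millimetres on both axes; metres are a rendering (see [predict_tbl()]).
#'
#' @param model_id short label.
#' @param form `"LINEAR"` or `"LOG10LOG10"`.
#' @param predictor `"poW"` or `"prW"` — which zygapophyseal width the
#'   model expects.
#' @param slope,intercept regression coefficients.
#' @param n,r2,p_slope,se_pred optional fit statistics (sample size,
#'   coefficient of determination, two-sided slope p-value, residual
#'   prediction error on the response scale in mm).
#' @param provenance `"BUILTIN"` for the shipped equations, `"FITTED"` for
#'   models produced by [fit_allometry()].
#' @return object of class `allometric_model`.
#' @export
allometric_model <- function(model_id, form = c("LINEAR", "LOG10LOG10"),
                             predictor = c("poW", "prW"), slope, intercept,
                             n = NA_integer_, r2 = NA_real_,
                             p_slope = NA_real_, se_pred = NA_real_,
                             provenance = c("BUILTIN", "FITTED")) {
  form <- match.arg(form)
  predictor <- match.arg(predictor)
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop_validation("r2 must be in [0,1]")
  structure(list(model_id = model_id, form = form, predictor = predictor,
                 slope = slope, intercept = intercept,
                 units_in = "mm", units_out = "mm",
                 n = n, r2 = r2, p_slope = p_slope, se_pred = se_pred,
                 provenance = provenance),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  eq <- if (x$form == "LINEAR")
    sprintf("tbl_mm = %.4g * %s_mm + %.4g", x$slope, x$predictor, x$intercept)
  else
    sprintf("log10(tbl_mm) = %.4g * log10(%s_mm) + %.4g",
            x$slope, x$predictor, x$intercept)
  cat("<allometric_model>", x$model_id, paste0("[", x$provenance, "]\n  "),
      eq, "\n")
  if (!is.na(x$r2)) cat(sprintf("  n = %s, r2 = %.3f\n", x$n, x$r2))
  invisible(x)
}

#' Built-in predictive body-length equations
#'
#' The three regressions used for madtsoiid size estimation, in mm:
#' \describe{
#'   \item{A60}{`tbl = 100.72 * poW + 436.24` — boine dataset, vertebrae
#'     60\% along the column (trans-postzygapophyseal width).}
#'   \item{A65}{`tbl = 105.98 * poW + 390` — boine dataset, 65\% position.}
#'   \item{C}{`log10(tbl) = 1.0739 * log10(prW) + 1.9842` — broad extant
#'     snake sample on trans-prezygapophyseal width, log10-log10.}
#' }
#'
#' @return named list of three `allometric_model` objects (`A60`, `A65`,
#'   `C`), provenance `BUILTIN`.
#' @export
builtin_models <- function() {
  list(
    A60 = allometric_model("A60", "LINEAR", "poW", 100.72, 436.24),
    A65 = allometric_model("A65", "LINEAR", "poW", 105.98, 390),
    C   = allometric_model("C", "LOG10LOG10", "prW", 1.0739, 1.9842)
  )
}

#' Predict total body length from a vertebral width
#'
#' @param model an [allometric_model()].
#' @param width_mm zygapophyseal width in mm, > 0 (vectorized).
#' @return numeric vector of class `tbl_estimate`: TBL in mm, with the
#'   metres rendering available via [tbl_m()].
#' @examples
#' m <- builtin_models()$C
#' tbl_m(predict_tbl(m, 111.4))  # 15.2
#' @export
predict_tbl <- function(model, width_mm) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.finite(width_mm)) || any(width_mm <= 0))
    stop_validation("width_mm must be finite and > 0")
  mm <- if (model$form == "LINEAR") {
    model$slope * width_mm + model$intercept
  } else {
    10^(model$slope * log10(width_mm) + model$intercept)
  }
  structure(mm, class = "tbl_estimate")
}

#' Render a TBL estimate in metres
#'
#' @param tbl_mm TBL in mm (a [predict_tbl()] result or plain numeric).
#' @param decimals decimals for the half-up rounding (default 1, the
#'   conventional reporting precision).
#' @return numeric, metres.
#' @export
tbl_m <- function(tbl_mm, decimals = 1) {
  round_half_up(unclass(tbl_mm) / 1000, decimals)
}

#' @export
print.tbl_estimate <- function(x, ...) {
  cat(sprintf("TBL %.0f mm (%.1f m)\n", unclass(x), tbl_m(x)))
  invisible(x)
}

#' Invert an allometric model: width from total body length
#'
#' Exact algebraic inverse of [predict_tbl()], so that
#' `predict_tbl(m, inverse_width(m, y))` returns `y` to within 1e-9
#' relative error.
#'
#' @param model an [allometric_model()].
#' @param tbl_mm TBL in mm; must exceed the intercept for `LINEAR`
#'   (positive-width domain) and be > 0 for `LOG10LOG10`.
#' @return width in mm.
#' @export
inverse_width <- function(model, tbl_mm) {
  stopifnot(inherits(model, "allometric_model"))
  tbl_mm <- unclass(tbl_mm)
  if (model$form == "LINEAR") {
    if (any(tbl_mm <= model$intercept))
      stop_validation("tbl_mm must exceed the intercept for a LINEAR model")
    (tbl_mm - model$intercept) / model$slope
  } else {
    if (any(tbl_mm <= 0)) stop_validation("tbl_mm must be > 0")
    10^((log10(tbl_mm) - model$intercept) / model$slope)
  }
}

#' Construct a comparative width/length dataset
#'
#' @param taxon character vector.
#' @param width_mm,tbl_mm strictly positive numeric vectors.
#' @param source_tag free-text provenance label.
#' @return object of class `comparative_dataset` (a data.frame).
#' @export
comparative_dataset <- function(taxon, width_mm, tbl_mm, source_tag = "") {
  stopifnot(length(taxon) == length(width_mm),
            length(width_mm) == length(tbl_mm))
  if (any(width_mm <= 0) || any(tbl_mm <= 0))
    stop_validation("widths and TBLs must be strictly positive")
  df <- data.frame(taxon = as.character(taxon), width_mm = width_mm,
                   tbl_mm = tbl_mm, stringsAsFactors = FALSE)
  attr(df, "source_tag") <- source_tag
  class(df) <- c("comparative_dataset", "data.frame")
  df
}

#' Read a comparative dataset CSV (`taxon,width_mm,tbl_mm`)
#' @param path CSV path.
#' @return a [comparative_dataset()].
#' @export
read_comparative_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon", "width_mm", "tbl_mm")
  if (!all(need %in% names(df)))
    stop_validation("comparative CSV needs columns taxon,width_mm,tbl_mm")
  comparative_dataset(df$taxon, df$width_mm, df$tbl_mm, source_tag = path)
}

#' Fit a TBL-on-width regression
#'
#' Ordinary least squares on raw mm (`LINEAR`) or after log10 transform of
#' both axes (`LOG10LOG10`, the standard normalizing transform for
#' power-law allometry). Reports r-squared, the two-sided slope t-test
#' p-value (n - 2 df) and a residual prediction error expressed on the
#' response (mm) scale — for the log-log form this is the one-sigma
#' multiplicative error evaluated at the geometric mean response.
#'
#' @param data a [comparative_dataset()].
#' @param form `"LINEAR"` or `"LOG10LOG10"`.
#' @param predictor which width the data represent (label only).
#' @param model_id label for the fitted model.
#' @return an `allometric_model` with `provenance = "FITTED"`; the fitted
#'   `lm` object and the data are attached as attributes for interval
#'   computation.
#' @export
fit_allometry <- function(data, form = c("LINEAR", "LOG10LOG10"),
                          predictor = c("poW", "prW"), model_id = "fitted") {
  stopifnot(inherits(data, "comparative_dataset"))
  form <- match.arg(form)
  predictor <- match.arg(predictor)
  if (nrow(data) < 3) stop_validation("need n >= 3 rows to fit")
  x <- data$width_mm; y <- data$tbl_mm
  if (form == "LOG10LOG10") { x <- log10(x); y <- log10(y) }
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop_validation("degenerate design: zero variance in predictor")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  sm <- summary(fit)
  sigma <- sm$sigma
  se_pred <- if (form == "LINEAR") sigma
             else (10^sigma - 1) * 10^mean(y)  # 1-sigma multiplicative error
  m <- allometric_model(model_id, form, predictor,
                        slope = unname(stats::coef(fit)[2]),
                        intercept = unname(stats::coef(fit)[1]),
                        n = nrow(data), r2 = sm$r.squared,
                        p_slope = unname(sm$coefficients[2, 4]),
                        se_pred = se_pred, provenance = "FITTED")
  attr(m, "fit") <- fit
  attr(m, "data") <- data
  m
}

#' Prediction interval for a fitted allometric model
#'
#' Standard OLS prediction interval at a new width, symmetric on the
#' fitted scale and back-transformed to mm for `LOG10LOG10` models.
#'
#' @param model a `FITTED` [allometric_model()] (from [fit_allometry()]).
#' @param width_mm new width, > 0.
#' @param level coverage in (0, 1), e.g. 0.95.
#' @return named numeric `c(lower, upper)` in mm.
#' @export
prediction_interval <- function(model, width_mm, level = 0.95) {
  stopifnot(inherits(model, "allometric_model"))
  if (model$provenance != "FITTED" || is.null(attr(model, "fit")))
    stop_validation("prediction intervals need a FITTED model with its data")
  if (level <= 0 || level >= 1) stop_validation("level must be in (0, 1)")
  if (any(width_mm <= 0)) stop_validation("width_mm must be > 0")
  x <- if (model$form == "LOG10LOG10") log10(width_mm) else width_mm
  pr <- stats::predict(attr(model, "fit"),
                       newdata = data.frame(x = x),
                       interval = "prediction", level = level)
  lo <- pr[, "lwr"]; hi <- pr[, "upr"]
  if (model$form == "LOG10LOG10") { lo <- 10^lo; hi <- 10^hi }
  c(lower = unname(lo), upper = unname(hi))
}

#' Serialize an allometric model to JSON
#' @param model an [allometric_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model)[!vapply(unclass(model), is.null, TRUE)],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
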