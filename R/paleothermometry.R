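# Metabolic-scaling paleothermometry: mean annual paleotemperature from the
# maximum body length of a poikilotherm, anchored to a modern analogue.
#
# The model: a poikilotherm's maximum attainable length is limited by
# ambient temperature through mass-specific metabolic rate. If the modern
# analogue reaches TBL_M metres at mean annual temperature MAT, a fossil
# taxon of maximum length TBL_v implies
#
#   MAPT = MAT + 3 * alpha * 10 C * log10(TBL_v / TBL_M) / log10(Q10)
#
# with Q10 the metabolic rate ratio per 10 C and alpha the metabolic
# scaling exponent. With the default alpha = 0.17 the leading coefficient
# 3*alpha*10 equals 5.1 exactly, and log10(2.6) ~= 0.415; the SIMPLIFIED
# form uses the printed constants 5.1 and 0.41.

#' Metabolic-scaling parameters for paleotemperature inference
#'
#' Defaults are the reticulated python calibration: present-day MAT of
#' 26.5 degC, analogue maximum length 10.05 m, pythonid Q10 of 2.6 and
#' metabolic scaling exponent 0.17.
#'
#' @param MAT present mean annual temperature at the analogue's range, degC.
#' @param TBL_M maximum total body length of the modern analogue, m (> 0).
#' @param Q10 metabolic-rate ratio per 10 degC (> 1).
#' @param alpha_scaling metabolic scaling exponent, in (0, 1).
#' @param form `"EXACT"` (uses `log10(Q10)`) or `"SIMPLIFIED"` (uses the
#'   conventional constants 5.1 / 0.41).
#' @return object of class `metabolic_params`.
#' @export
metabolic_params <- function(MAT = 26.5, TBL_M = 10.05, Q10 = 2.6,
                             alpha_scaling = 0.17,
                             form = c("EXACT", "SIMPLIFIED")) {
  form <- match.arg(form)
  if (TBL_M <= 0) stop_validation("TBL_M must be > 0")
  if (Q10 <= 1) stop_validation("Q10 must be > 1")
  if (alpha_scaling <= 0 || alpha_scaling >= 1)
    stop_validation("alpha_scaling must be in (0, 1)")
  structure(list(MAT = MAT, TBL_M = TBL_M, Q10 = Q10,
                 alpha_scaling = alpha_scaling, form = form),
            class = "metabolic_params")
}

#' Mean annual paleotemperature from maximum body length
#'
#' @param params a [metabolic_params()]; its `form` selects the exact or
#'   simplified coefficients.
#' @param tbl_v maximum estimated body length of the fossil taxon, m (> 0;
#'   vectorized).
#' @return MAPT in degC (full precision; round for reporting).
#' @examples
#' mapt(metabolic_params(), 10.05)                        # 26.5
#' mapt(metabolic_params(form = "SIMPLIFIED"), 15.2)      # ~28.7
#' @export
mapt <- function(params, tbl_v) {
  stopifnot(inherits(params, "metabolic_params"))
  if (any(!is.finite(tbl_v)) || any(tbl_v <= 0))
    stop_validation("tbl_v must be finite and > 0")
  ratio <- log10(tbl_v / params$TBL_M)
  if (params$form == "EXACT") {
    params$MAT + 3 * params$alpha_scaling * 10 * ratio / log10(params$Q10)
  } else {
    params$MAT + 5.1 * ratio / 0.41
  }
}

#' Temperature anomaly relative to the present
#'
#' `mapt(params, tbl_v) - MAT`: zero iff the fossil matches the analogue's
#' maximum length, negative for smaller taxa.
#'
#' @inheritParams mapt
#' @return Delta-T in degC.
#' @export
delta_t <- function(params, tbl_v) {
  mapt(params, tbl_v) - params$MAT
}

#' Side-by-side MAPT report
#'
#' Evaluates both equation forms at one or more body lengths and reports
#' their difference, rounded half-up to one decimal for display columns
#' while retaining full precision.
#'
#' @param tbl_v body length(s), m.
#' @param params a [metabolic_params()] (its `form` field is ignored; both
#'   forms are computed).
#' @return data.frame with columns `tbl_v_m`, `mapt_exact_c`,
#'   `mapt_simplified_c`, `delta_t_exact_c`, `delta_t_simplified_c`,
#'   `form_difference_c`.
#' @export
mapt_report <- function(tbl_v, params = metabolic_params()) {
  pe <- metabolic_params(params$MAT, params$TBL_M, params$Q10,
                         params$alpha_scaling, "EXACT")
  ps <- metabolic_params(params$MAT, params$TBL_M, params$Q10,
                         params$alpha_scaling, "SIMPLIFIED")
  me <- mapt(pe, tbl_v); ms <- mapt(ps, tbl_v)
  data.frame(tbl_v_m = tbl_v,
             mapt_exact_c = me,
             mapt_simplified_c = ms,
             delta_t_exact_c = me - params$MAT,
             delta_t_simplified_c = ms - params$MAT,
             form_difference_c = me - ms)
}

#' Write a MAPT report as JSON
#' @param report a [mapt_report()] data.frame.
#' @param params the [metabolic_params()] used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapt_json <- function(report, params, path) {
  jsonlite::write_json(list(params = unclass(params), report = report),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
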