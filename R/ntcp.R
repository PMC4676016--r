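#' @name ntcp-params
#' @title Toxicity model parameter sets
#'
#' @description Constructors for the lung and chest-wall toxicity models.
#'
#' * `lkb_params()`: Lyman-Kutcher-Burman probit with volume-effect exponent
#'   `n_volume` = 1.00 (mean-dose organ), slope `m` = 0.45 and
#'   `td50` = 26.8 Gy, for radiation pneumonitis after EQD2 conversion with
#'   the lung alpha/beta.
#' * `fenwick_ntcp_params()`: probit in mean lung dose. The source parameters
#'   are not published alongside the other defaults, so `d50` and `m` have
#'   **no default values** and must be supplied explicitly (e.g. from a
#'   config file); constructing the set without them is an error.
#' * `meud_params()`: modified EUD of the hottest `volume_cap` cc of chest
#'   wall with power-mean exponent `exponent_alpha` = 5 (moderate weighting)
#'   and `volume_cap` = 100 cc.
#' @param n_volume,m,td50,d50,exponent_alpha,volume_cap Model parameters,
#'   see Description.
#' @return A named list with a class tag.
NULL

#' @rdname ntcp-params
#' @export
lkb_params <- function(n_volume = 1.00, m = 0.45, td50 = 26.8) {
  stopifnot(n_volume > 0, m > 0, td50 > 0)
  structure(list(n_volume = n_volume, m = m, td50 = td50),
            class = "lkb_params")
}

#' @rdname ntcp-params
#' @export
fenwick_ntcp_params <- function(d50, m) {
  if (missing(d50) || missing(m)) {
    stop("fenwick_ntcp_params has no defaults: supply d50 and m explicitly")
  }
  stopifnot(is.numeric(d50), d50 > 0, is.numeric(m), m > 0)
  structure(list(d50 = d50, m = m), class = "fenwick_ntcp_params")
}

#' @rdname ntcp-params
#' @export
meud_params <- function(exponent_alpha = 5, volume_cap = 100) {
  stopifnot(exponent_alpha >= 1, volume_cap > 0)
  structure(list(exponent_alpha = exponent_alpha, volume_cap = volume_cap),
            class = "meud_params")
}

#' Generalized equivalent uniform dose (power-mean DVH reduction)
#'
#' `gEUD = (sum_i v_i D_i^(1/n))^n`. With the volume-effect exponent
#' `n_volume = 1` this is exactly the mean dose; smaller exponents weight hot
#' regions more strongly.
#'
#' @param ddvh A [ddvh()] with positive total volume.
#' @param n_volume Volume-effect exponent (> 0).
#' @return gEUD in Gy.
#' @export
generalized_eud <- function(ddvh, n_volume = 1) {
  stopifnot(inherits(ddvh, "ddvh"))
  if (ddvh$total_volume <= 0) stop("zero total volume")
  if (!is.numeric(n_volume) || n_volume <= 0) stop("n_volume must be > 0")
  v <- volume_fractions(ddvh)
  sum(v * ddvh$dose^(1 / n_volume))^n_volume
}

#' LKB lung NTCP
#'
#' Lyman-Kutcher-Burman probit model on the EQD2-converted lung DVH:
#' `NTCP = Phi((gEUD - TD50) / (m TD50))` with the gEUD of
#' [generalized_eud()]. With `n_volume = 1` the model depends on the DVH
#' only through mean lung dose.
#'
#' @param lung_ddvh_eqd2 EQD2-converted lung [ddvh()] (lung alpha/beta,
#'   1.3 Gy).
#' @param params An [lkb_params()].
#' @return NTCP in `[0, 1]`.
#' @export
ntcp_lkb <- function(lung_ddvh_eqd2, params = lkb_params()) {
  .check_eqd2(lung_ddvh_eqd2)
  geud <- generalized_eud(lung_ddvh_eqd2, params$n_volume)
  stats::pnorm((geud - params$td50) / (params$m * params$td50))
}

#' Fenwick mean-lung-dose NTCP
#'
#' Probit in mean lung dose: `NTCP = Phi((MLD - d50) / (m d50))`. Parameters
#' must be supplied explicitly via [fenwick_ntcp_params()]; there are no
#' built-in defaults.
#'
#' @param mean_lung_dose_eqd2 Mean lung dose in EQD2 Gy (>= 0).
#' @param params A [fenwick_ntcp_params()].
#' @return NTCP in `[0, 1]`.
#' @export
ntcp_fenwick_lung <- function(mean_lung_dose_eqd2, params) {
  if (missing(params) || is.null(params)) {
    stop("Fenwick lung-NTCP parameters are not configured; ",
         "supply fenwick_ntcp_params(d50, m)")
  }
  stopifnot(inherits(params, "fenwick_ntcp_params"))
  if (mean_lung_dose_eqd2 < 0) stop("mean lung dose must be >= 0")
  stats::pnorm((mean_lung_dose_eqd2 - params$d50) / (params$m * params$d50))
}

#' Modified EUD of the chest wall
#'
#' Restricts the EQD2-converted chest-wall DVH to its hottest `volume_cap` cc
#' (default 100 cc) and returns the power mean of bin doses with exponent
#' `exponent_alpha` (default 5, moderate high-dose weighting):
#' `mEUD = (sum_i w_i D_i^alpha)^(1/alpha)` with
#' `w_i = V_i / min(volume_cap, V_total)`. Uniform dose over the cap returns
#' itself; the score is on the EQD2 Gy scale.
#'
#' @param cw_ddvh_eqd2 EQD2-converted chest-wall [ddvh()] (chest-wall
#'   alpha/beta, 3 Gy).
#' @param params A [meud_params()].
#' @return mEUD score (Gy-equivalent, >= 0).
#' @export
meud_chest_wall <- function(cw_ddvh_eqd2, params = meud_params()) {
  .check_eqd2(cw_ddvh_eqd2)
  if (cw_ddvh_eqd2$total_volume <= 0) stop("empty chest-wall structure")
  hot <- hottest_subvolume(cw_ddvh_eqd2, params$volume_cap)
  w <- hot$volume / hot$total_volume
  a <- params$exponent_alpha
  sum(w * hot$dose^a)^(1 / a)
}

#' All toxicity models for one plan and scheme
#'
#' Converts the physical-dose lung and chest-wall DVHs to EQD2 with their
#' respective alpha/beta ratios, evaluates the LKB and (if configured)
#' Fenwick lung NTCP models and the chest-wall mEUD, and medians the
#' available lung NTCP values. When the Fenwick parameters are `NULL` the
#' model is skipped with a message and the lung median is taken over the
#' remaining model.
#'
#' @param lung_ddvh Physical-dose lung [ddvh()] (GTV already excluded).
#' @param cw_ddvh Physical-dose chest-wall [ddvh()].
#' @param scheme A [fraction_scheme()].
#' @param alpha_betas An [alpha_beta_set()].
#' @param params List with elements `lkb`, `fenwick_ntcp` (may be `NULL`) and
#'   `meud`; see [default_model_params()].
#' @param quiet Suppress the skip message.
#' @return A list of class `toxicity_result` with `lkb_ntcp`, `fenwick_ntcp`
#'   (`NA` when unconfigured), `median_lung_ntcp`, `cw_meud` and
#'   `mean_lung_dose_eqd2`.
#' @export
toxicity_all <- function(lung_ddvh, cw_ddvh, scheme,
                         alpha_betas = alpha_beta_set(),
                         params = default_model_params(), quiet = FALSE) {
  stopifnot(inherits(lung_ddvh, "ddvh"), inherits(cw_ddvh, "ddvh"))
  if (lung_ddvh$scale != "physical" || cw_ddvh$scale != "physical") {
    stop("toxicity_all expects physical-dose DVHs")
  }
  lung_eq <- convert_ddvh(lung_ddvh, scheme, alpha_betas$lung, "EQD2")
  cw_eq <- convert_ddvh(cw_ddvh, scheme, alpha_betas$chest_wall, "EQD2")
  lkb <- ntcp_lkb(lung_eq, params$lkb)
  mld <- mean_dose(lung_eq)
  if (is.null(params$fenwick_ntcp)) {
    if (!quiet) {
      message("Fenwick lung-NTCP parameters not configured; model skipped, ",
              "lung NTCP median taken over the LKB model only")
    }
    fen <- NA_real_
    med <- lkb
  } else {
    fen <- ntcp_fenwick_lung(mld, params$fenwick_ntcp)
    med <- stats::median(c(lkb, fen))
  }
  structure(
    list(lkb_ntcp = lkb, fenwick_ntcp = fen, median_lung_ntcp = med,
         cw_meud = meud_chest_wall(cw_eq, params$meud),
         mean_lung_dose_eqd2 = mld),
    class = "toxicity_result"
  )
}
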