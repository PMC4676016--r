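#' @name tcp-params
#' @title TCP model parameter sets
#'
#' @description Constructors for the parameter sets of the five tumor control
#' probability models. Defaults are the published clinical fits used for
#' NSCLC SBRT modeling; every value can be overridden, and the reference
#' volume of the Fenwick model (`v_ref`) is configurable because the source
#' does not fix it (the cohort median tumor volume, 4.9 cc, is used).
#'
#' * `martel_params()`: log-logistic dose response, `d50` = 84.5 Gy,
#'   normalized slope `gamma` = 1.5.
#' * `fenwick_tcp_params()`: probit with logarithmic volume correction,
#'   `d50` = 84.6 Gy, `m` = 0.329, `c` = 9.58 Gy per log-volume.
#' * `webb_nahum_params()`: Poisson cell-kill averaged over a Gaussian
#'   radiosensitivity distribution, `alpha_mean` = 0.30 / Gy,
#'   `alpha_sd` = 0.11 / Gy, clonogen density `rho` = 1e8 / cc.
#' * `eud_tcp_params()`: survival-based equivalent uniform dose with
#'   `alpha` = 0.30 / Gy, `tcd50` = 51.24 Gy, `gamma50` = 0.83.
#' * `nitin_params()`: logistic in BED10 with diameter correction,
#'   `c` = 10 Gy/cm, `tcd50` = 0 Gy, `k` = 31 Gy.
#' @param d50,gamma,m,c,v_ref,alpha_mean,alpha_sd,clonogen_density,tcd50,gamma50,alpha,k
#'   Model parameters, see Description.
#' @return A named list with a class tag.
NULL

#' @rdname tcp-params
#' @export
martel_params <- function(d50 = 84.5, gamma = 1.5) {
  stopifnot(d50 > 0, gamma > 0)
  structure(list(d50 = d50, gamma = gamma), class = "martel_params")
}

#' @rdname tcp-params
#' @export
fenwick_tcp_params <- function(d50 = 84.6, m = 0.329, c = 9.58,
                               v_ref = 4.9) {
  stopifnot(d50 > 0, m > 0, v_ref > 0)
  structure(list(d50 = d50, m = m, c = c, v_ref = v_ref),
            class = "fenwick_tcp_params")
}

#' @rdname tcp-params
#' @export
webb_nahum_params <- function(alpha_mean = 0.30, alpha_sd = 0.11,
                              clonogen_density = 1e8) {
  stopifnot(alpha_mean > 0, alpha_sd >= 0, clonogen_density > 0)
  structure(
    list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         clonogen_density = clonogen_density),
    class = "webb_nahum_params"
  )
}

#' @rdname tcp-params
#' @export
eud_tcp_params <- function(tcd50 = 51.24, gamma50 = 0.83, alpha = 0.30) {
  stopifnot(tcd50 > 0, gamma50 > 0, alpha > 0)
  structure(list(tcd50 = tcd50, gamma50 = gamma50, alpha = alpha),
            class = "eud_tcp_params")
}

#' @rdname tcp-params
#' @export
nitin_params <- function(c = 10, tcd50 = 0, k = 31) {
  stopifnot(k > 0)
  structure(list(c = c, tcd50 = tcd50, k = k), class = "nitin_params")
}

#' Martel dose-response curve
#'
#' Log-logistic tumor control response
#' `1 / (1 + (d50 / D)^(4 gamma))`, which equals 0.5 at `D = d50` and has
#' normalized slope `gamma` there; 0 at zero dose.
#'
#' @param dose Uniform (EQD2) dose in Gy; vectorized, >= 0.
#' @param params A [martel_params()].
#' @return Control probability in `[0, 1]`.
#' @export
martel_dose_response <- function(dose, params = martel_params()) {
  if (any(dose < 0)) stop("dose must be >= 0")
  p <- ifelse(dose == 0, 0, 1 / (1 + (params$d50 / dose)^(4 * params$gamma)))
  as.numeric(p)
}

#' Combine per-bin responses over a DVH (standard approach)
#'
#' Voxel-independence combination: the whole-structure probability is the
#' product over bins of the per-bin response raised to the relative volume,
#' `prod_i r(D_i)^(v_i)`. A cold bin with zero response and positive volume
#' forces the combined probability to zero.
#'
#' @param response_fn Function mapping a dose vector to probabilities.
#' @param ddvh_eqd2 An EQD2-tagged [ddvh()].
#' @return Combined probability.
#' @export
combine_bins <- function(response_fn, ddvh_eqd2) {
  stopifnot(inherits(ddvh_eqd2, "ddvh"))
  if (length(ddvh_eqd2$dose) == 0L) stop("empty DVH")
  v <- volume_fractions(ddvh_eqd2)
  r <- response_fn(ddvh_eqd2$dose)
  keep <- v > 0
  prod(r[keep]^v[keep])
}

.check_eqd2 <- function(ddvh) {
  if (ddvh$scale != "EQD2") {
    stop("DVH must be EQD2-converted (scale tag is '", ddvh$scale, "')")
  }
  invisible(ddvh)
}

#' Martel TCP from an EQD2 differential DVH
#'
#' @param ddvh_eqd2 EQD2-converted GTV [ddvh()].
#' @param params A [martel_params()].
#' @return TCP in `[0, 1]`.
#' @export
tcp_martel <- function(ddvh_eqd2, params = martel_params()) {
  .check_eqd2(ddvh_eqd2)
  combine_bins(function(d) martel_dose_response(d, params), ddvh_eqd2)
}

#' Fenwick TCP with volume correction
#'
#' Probit dose response with a logarithmic tumor-volume adjustment,
#' `Phi((D - d50 - c log(V / v_ref)) / (m d50))`, evaluated per DVH bin and
#' combined with [combine_bins()]. Larger tumors have lower control at the
#' same dose.
#'
#' @param ddvh_eqd2 EQD2-converted GTV [ddvh()].
#' @param tumor_volume Tumor volume in cc (> 0).
#' @param params A [fenwick_tcp_params()].
#' @return TCP in `[0, 1]`.
#' @export
tcp_fenwick <- function(ddvh_eqd2, tumor_volume,
                        params = fenwick_tcp_params()) {
  .check_eqd2(ddvh_eqd2)
  if (!is.numeric(tumor_volume) || tumor_volume <= 0) {
    stop("tumor_volume must be > 0")
  }
  shift <- params$d50 + params$c * log(tumor_volume / params$v_ref)
  sd <- params$m * params$d50
  combine_bins(function(d) stats::pnorm((d - shift) / sd), ddvh_eqd2)
}

#' Webb-Nahum population-averaged Poisson TCP
#'
#' Poisson tumor control `exp(-rho sum_i V_i exp(-alpha D_i))` averaged over
#' a Gaussian distribution of radiosensitivity alpha (mean `alpha_mean`, sd
#' `alpha_sd`) truncated to alpha > 0 and renormalized. Doses are EQD2, so
#' cell kill uses the linear term only. The alpha integral is evaluated by
#' Gauss-Legendre quadrature (256 nodes on
#' `[max(0, mean - 6 sd), mean + 6 sd]`), which is exact to well below 1e-6
#' for this smooth integrand; with `alpha_sd = 0` the degenerate closed form
#' is used.
#'
#' @param ddvh_eqd2 EQD2-converted GTV [ddvh()] (absolute volumes in cc).
#' @param params A [webb_nahum_params()].
#' @param nodes Number of quadrature nodes.
#' @return TCP in `[0, 1]`.
#' @export
tcp_webb_nahum <- function(ddvh_eqd2, params = webb_nahum_params(),
                           nodes = 256L) {
  .check_eqd2(ddvh_eqd2)
  if (ddvh_eqd2$total_volume <= 0) stop("zero total volume")
  rho <- params$clonogen_density
  mu <- params$alpha_mean
  sg <- params$alpha_sd
  surv <- function(a) {
    # expected surviving clonogens at radiosensitivity a (vectorized in a)
    s <- vapply(a, function(ai) {
      sum(ddvh_eqd2$volume * exp(-ai * ddvh_eqd2$dose))
    }, 0)
    exp(-rho * s)
  }
  if (sg == 0) return(surv(mu))
  lo <- max(0, mu - 6 * sg)
  hi <- mu + 6 * sg
  gl <- pracma::gaussLegendre(nodes, lo, hi)
  z <- stats::pnorm(hi, mu, sg) - stats::pnorm(lo, mu, sg)  # truncated mass
  sum(gl$w * stats::dnorm(gl$x, mu, sg) * surv(gl$x)) / z
}

#' Survival-based equivalent uniform dose
#'
#' `EUD = -(1/alpha) log(sum_i v_i exp(-alpha D_i))`: the uniform dose giving
#' the same average clonogen survival as the inhomogeneous distribution.
#' Dominated by cold spots. Computed with a log-sum-exp guard so very high
#' doses do not underflow.
#'
#' @param ddvh_eqd2 EQD2-converted [ddvh()].
#' @param alpha Radiosensitivity in 1/Gy (> 0).
#' @return EUD in Gy.
#' @export
cell_kill_eud <- function(ddvh_eqd2, alpha = 0.30) {
  stopifnot(inherits(ddvh_eqd2, "ddvh"), alpha > 0)
  v <- volume_fractions(ddvh_eqd2)
  keep <- v > 0
  x <- -alpha * ddvh_eqd2$dose[keep] + log(v[keep])
  m <- max(x)
  -(m + log(sum(exp(x - m)))) / alpha
}

#' EUD-based TCP
#'
#' Reduces the DVH to the survival-based EUD ([cell_kill_eud()]) and applies
#' the log-logistic response `1 / (1 + (tcd50 / EUD)^(4 gamma50))`, which is
#' 0.5 at `EUD = tcd50`.
#'
#' @param ddvh_eqd2 EQD2-converted GTV [ddvh()].
#' @param params An [eud_tcp_params()].
#' @return TCP in `[0, 1]`.
#' @export
tcp_eud <- function(ddvh_eqd2, params = eud_tcp_params()) {
  .check_eqd2(ddvh_eqd2)
  eud <- cell_kill_eud(ddvh_eqd2, params$alpha)
  if (eud <= 0) return(0)
  1 / (1 + (params$tcd50 / eud)^(4 * params$gamma50))
}

#' Nitin BED-based TCP
#'
#' Logistic dose response in BED10 with a linear correction for maximal tumor
#' diameter: `TCP = 1 / (1 + exp((tcd50 + c L - BED10) / k))`. BED10 is
#' computed from the mean physical GTV dose delivered in the scheme's number
#' of fractions (`dose_basis = "mean_gtv"`, default) or from the prescription
#' dose (`"prescription"`).
#'
#' @param scheme A [fraction_scheme()].
#' @param gtv_ddvh Physical-dose GTV [ddvh()] (used for the mean-dose basis).
#' @param tumor_diameter Maximal tumor diameter in cm (> 0).
#' @param params A [nitin_params()].
#' @param dose_basis `"mean_gtv"` or `"prescription"`.
#' @param alpha_beta Alpha/beta for the BED conversion (Gy); default 10.
#' @return TCP in `[0, 1]`.
#' @export
tcp_nitin <- function(scheme, gtv_ddvh = NULL, tumor_diameter,
                      params = nitin_params(),
                      dose_basis = c("mean_gtv", "prescription"),
                      alpha_beta = 10) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  dose_basis <- match.arg(dose_basis)
  if (!is.numeric(tumor_diameter) || tumor_diameter <= 0) {
    stop("tumor_diameter must be > 0")
  }
  bed10 <- if (dose_basis == "prescription") {
    bed(scheme, alpha_beta)
  } else {
    if (is.null(gtv_ddvh)) stop("mean_gtv basis requires gtv_ddvh")
    if (gtv_ddvh$scale != "physical") {
      stop("Nitin mean-dose basis requires a physical-dose GTV DVH")
    }
    .bed_total(mean_dose(gtv_ddvh), scheme$n_fractions, alpha_beta)
  }
  1 / (1 + exp((params$tcd50 + params$c * tumor_diameter - bed10) / params$k))
}

#' All five TCP models for one plan and scheme
#'
#' Converts the physical-dose GTV DVH to EQD2 with the tumor alpha/beta,
#' evaluates the Martel, Fenwick, Webb-Nahum, EUD-based and Nitin models and
#' returns the per-model values together with their median (the headline
#' TCP statistic).
#'
#' @param gtv_ddvh Physical-dose GTV [ddvh()].
#' @param scheme A [fraction_scheme()].
#' @param tumor_volume Tumor volume in cc.
#' @param tumor_diameter Maximal tumor diameter in cm.
#' @param params List of model parameter sets, see [default_model_params()].
#' @param alpha_beta Tumor alpha/beta in Gy; default 10.
#' @return A list of class `tcp_result` with elements `per_model` (named
#'   numeric vector: martel, fenwick, webb_nahum, eud, nitin) and
#'   `median_tcp`.
#' @export
tcp_all <- function(gtv_ddvh, scheme, tumor_volume, tumor_diameter,
                    params = default_model_params(), alpha_beta = 10) {
  stopifnot(inherits(gtv_ddvh, "ddvh"))
  if (gtv_ddvh$scale != "physical") {
    stop("tcp_all expects a physical-dose GTV DVH")
  }
  eq <- convert_ddvh(gtv_ddvh, scheme, alpha_beta, "EQD2")
  per <- c(
    martel = tcp_martel(eq, params$martel),
    fenwick = tcp_fenwick(eq, tumor_volume, params$fenwick_tcp),
    webb_nahum = tcp_webb_nahum(eq, params$webb_nahum),
    eud = tcp_eud(eq, params$eud),
    nitin = tcp_nitin(scheme, gtv_ddvh, tumor_diameter, params$nitin)
  )
  structure(list(per_model = per, median_tcp = stats::median(per)),
            class = "tcp_result")
}
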