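#' Fraction scheme
#'
#' A radiotherapy regimen of `n_fractions` fractions of `dose_per_fraction`
#' Gy each (e.g. the SBRT schedule 4 x 12 Gy).
#'
#' @param n_fractions Number of fractions (integer >= 1).
#' @param dose_per_fraction Dose per fraction in Gy (> 0).
#' @param label Scheme label; default `"<n>x<d>"`.
#' @return An object of class `fraction_scheme` with the two fields plus
#'   `total_dose = n_fractions * dose_per_fraction`.
#' @examples
#' fraction_scheme(4, 12)$total_dose  # 48 Gy
#' @export
fraction_scheme <- function(n_fractions, dose_per_fraction,
                            label = sprintf("%dx%g", n_fractions,
                                            dose_per_fraction)) {
  if (!is.numeric(n_fractions) || n_fractions < 1 ||
      n_fractions != round(n_fractions)) {
    stop("n_fractions must be a positive integer")
  }
  if (!is.numeric(dose_per_fraction) || dose_per_fraction <= 0) {
    stop("dose_per_fraction must be > 0")
  }
  structure(
    list(
      n_fractions = as.integer(n_fractions),
      dose_per_fraction = as.numeric(dose_per_fraction),
      total_dose = as.integer(n_fractions) * as.numeric(dose_per_fraction),
      label = as.character(label)[1L]
    ),
    class = "fraction_scheme"
  )
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat(sprintf("Fraction scheme %s: %d x %g Gy (total %g Gy)\n",
              x$label, x$n_fractions, x$dose_per_fraction, x$total_dose))
  invisible(x)
}

#' The ten studied SBRT fraction schemes
#'
#' The default scheme list: 1x25, 1x30, 1x34, 3x15, 3x18, 3x20, 4x12, 5x12,
#' 6x10 and 10x7 Gy.
#'
#' @return A named list of [fraction_scheme()] objects.
#' @export
default_schemes <- function() {
  spec <- list(
    c(1, 25), c(1, 30), c(1, 34), c(3, 15), c(3, 18),
    c(3, 20), c(4, 12), c(5, 12), c(6, 10), c(10, 7)
  )
  out <- lapply(spec, function(s) fraction_scheme(s[1L], s[2L]))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Tissue alpha/beta ratios
#'
#' Linear-quadratic alpha/beta ratios (Gy) used throughout: 10 Gy for the
#' tumor, 1.3 Gy for lung and 3 Gy for the chest wall.
#'
#' @param tumor,lung,chest_wall Alpha/beta values in Gy (> 0).
#' @return A list of class `alpha_beta_set`.
#' @export
alpha_beta_set <- function(tumor = 10, lung = 1.3, chest_wall = 3) {
  vals <- c(tumor = tumor, lung = lung, chest_wall = chest_wall)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("alpha/beta ratios must be positive")
  }
  structure(as.list(vals), class = "alpha_beta_set")
}

#' Biologically effective dose of a fraction scheme
#'
#' BED = n d (1 + d / (alpha/beta)). With alpha/beta = 10 Gy this is the
#' BED10 used to rank lung-tumor schemes.
#'
#' @param scheme A [fraction_scheme()].
#' @param alpha_beta Alpha/beta ratio in Gy (> 0); default 10.
#' @return BED in Gy.
#' @examples
#' bed(fraction_scheme(4, 12))  # 105.6
#' @export
bed <- function(scheme, alpha_beta = 10) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) {
    stop("alpha_beta must be > 0")
  }
  n <- scheme$n_fractions
  d <- scheme$dose_per_fraction
  n * d * (1 + d / alpha_beta)
}

# BED of a total dose delivered in n equal fractions (per-bin form)
.bed_total <- function(total_dose, n_fractions, alpha_beta) {
  total_dose * (1 + total_dose / (n_fractions * alpha_beta))
}

#' Equieffective dose in 2 Gy fractions (EQD2)
#'
#' Converts a total physical dose delivered in `n_fractions` equal fractions
#' to the equieffective total dose in 2 Gy fractions under the
#' linear-quadratic model:
#' EQD2 = D (d + alpha/beta) / (2 + alpha/beta), with d = D / n.
#'
#' @param total_dose Total physical dose in Gy (>= 0); vectorized.
#' @param n_fractions Number of fractions (>= 1).
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy.
#' @examples
#' eqd2_total(48, 4, 10)  # 88 Gy
#' @export
eqd2_total <- function(total_dose, n_fractions, alpha_beta) {
  if (any(total_dose < 0)) stop("total_dose must be >= 0")
  if (!is.numeric(n_fractions) || n_fractions < 1) {
    stop("n_fractions must be >= 1")
  }
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) {
    stop("alpha_beta must be > 0")
  }
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Convert a physical-dose differential DVH to EQD2 or BED
#'
#' Maps each bin dose through the linear-quadratic conversion, assuming every
#' volume element receives its total dose in the scheme's `n_fractions` equal
#' fractions (per-bin fraction size = bin dose / n). Volumes are unchanged and
#' the output is tagged with the target scale; converting an already-converted
#' DVH is an error.
#'
#' @param ddvh A physical-dose [ddvh()].
#' @param scheme A [fraction_scheme()] (only `n_fractions` enters).
#' @param alpha_beta Tissue alpha/beta ratio in Gy.
#' @param target `"EQD2"` or `"BED"`.
#' @return A [ddvh()] tagged `target`.
#' @export
convert_ddvh <- function(ddvh, scheme, alpha_beta,
                         target = c("EQD2", "BED")) {
  stopifnot(inherits(ddvh, "ddvh"), inherits(scheme, "fraction_scheme"))
  target <- match.arg(target)
  if (ddvh$scale != "physical") {
    stop("input DVH is on the '", ddvh$scale,
         "' scale; conversion requires physical dose")
  }
  n <- scheme$n_fractions
  dose <- if (target == "EQD2") {
    eqd2_total(ddvh$dose, n, alpha_beta)
  } else {
    .bed_total(ddvh$dose, n, alpha_beta)
  }
  ddvh(dose, ddvh$volume, total_volume = ddvh$total_volume,
       structure = ddvh$structure, scale = target)
}
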