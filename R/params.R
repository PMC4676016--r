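#' Default model parameter bundle
#'
#' Collects the parameter sets of all eight outcome models in one list, as
#' consumed by [tcp_all()], [toxicity_all()] and [evaluate_cohort()]. The
#' Fenwick lung-NTCP slot defaults to `NULL` (unconfigured) because its
#' published parameters are not part of the default set; supply
#' [fenwick_ntcp_params()] explicitly or via a config file to enable it.
#'
#' @param martel,fenwick_tcp,webb_nahum,eud,nitin,lkb,fenwick_ntcp,meud
#'   Individual parameter sets; see [tcp-params] and [ntcp-params].
#' @return A named list of class `model_params`.
#' @export
default_model_params <- function(martel = martel_params(),
                                 fenwick_tcp = fenwick_tcp_params(),
                                 webb_nahum = webb_nahum_params(),
                                 eud = eud_tcp_params(),
                                 nitin = nitin_params(),
                                 lkb = lkb_params(),
                                 fenwick_ntcp = NULL,
                                 meud = meud_params()) {
  structure(
    list(martel = martel, fenwick_tcp = fenwick_tcp,
         webb_nahum = webb_nahum, eud = eud, nitin = nitin,
         lkb = lkb, fenwick_ntcp = fenwick_ntcp, meud = meud),
    class = "model_params"
  )
}

.build_params_from_list <- function(x) {
  if (is.null(x)) return(default_model_params())
  grab <- function(name, ctor) {
    if (is.null(x[[name]])) ctor() else do.call(ctor, x[[name]])
  }
  default_model_params(
    martel = grab("martel", martel_params),
    fenwick_tcp = grab("fenwick_tcp", fenwick_tcp_params),
    webb_nahum = grab("webb_nahum", webb_nahum_params),
    eud = grab("eud", eud_tcp_params),
    nitin = grab("nitin", nitin_params),
    lkb = grab("lkb", lkb_params),
    fenwick_ntcp = if (is.null(x$fenwick_ntcp)) NULL else {
      do.call(fenwick_ntcp_params, x$fenwick_ntcp)
    },
    meud = grab("meud", meud_params)
  )
}

#' Read an analysis configuration file
#'
#' Reads a YAML (or JSON) configuration with optional sections `schemes`
#' (list of `{label, n_fractions, dose_per_fraction}`), `alpha_beta`
#' (`tumor`, `lung`, `chest_wall`), `tcp_models` / `toxicity_models`
#' (per-model parameter overrides), `generator` (arguments of
#' [cohort_spec()]) and `decision_rule` (`reference_scheme`, `ntcp_margin`,
#' `meud_margin`). Missing sections fall back to package defaults; unknown
#' model parameters are an error.
#'
#' @param path Path to the YAML/JSON file.
#' @return A list with elements `schemes`, `alpha_betas`, `params`,
#'   `cohort_spec`, `decision_rule`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  schemes <- if (is.null(cfg$schemes)) default_schemes() else {
    out <- lapply(cfg$schemes, function(s) {
      if (is.null(s$n_fractions) || is.null(s$dose_per_fraction)) {
        stop("each scheme needs n_fractions and dose_per_fraction")
      }
      if (is.null(s$label)) {
        fraction_scheme(s$n_fractions, s$dose_per_fraction)
      } else {
        fraction_scheme(s$n_fractions, s$dose_per_fraction, s$label)
      }
    })
    names(out) <- vapply(out, `[[`, "", "label")
    out
  }
  ab <- if (is.null(cfg$alpha_beta)) alpha_beta_set() else {
    do.call(alpha_beta_set, cfg$alpha_beta)
  }
  params <- .build_params_from_list(c(cfg$tcp_models, cfg$toxicity_models))
  cs <- if (is.null(cfg$generator)) cohort_spec() else {
    do.call(cohort_spec, cfg$generator)
  }
  dr <- list(reference_scheme = "4x12", ntcp_margin = 0.03,
             meud_margin = 0.35)
  dr[names(cfg$decision_rule)] <- cfg$decision_rule
  list(schemes = schemes, alpha_betas = ab, params = params,
       cohort_spec = cs, decision_rule = dr)
}
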