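#' Synthetic cohort specification
#'
#' Parameters of the synthetic SBRT cohort generator. The defaults emulate a
#' 16-patient peripheral-NSCLC cohort: the default tumor volumes are the
#' sixteen observed GTV volumes (0.9-11.6 cc, ascending); plans cover the
#' GTV at relative dose 1.0 with a hotspot of 120-130% centered in the GTV;
#' lung dose falls off exponentially with a tail scale tied to the
#' lung-to-tumor volume ratio R; chest-wall dose peaks at
#' `hotspot * exp(-D / cw_lambda)` for tumor-to-chest-wall distance D (mm).
#'
#' Patients are assigned deterministically to risk strata so that both lung
#' strata (R <= 400 with D >= 15 mm, and its complement) and all three
#' distance bands (D <= 5.5, 5.5-15, >= 15 mm) are populated: the largest
#' quarter of tumors receives small lungs (low R) and a distant chest wall,
#' and the remainder cycles through the near/mid/far distance bands.
#'
#' @param n_patients Number of patients (default 16).
#' @param seed RNG seed; the generated cohort is a pure function of the spec.
#' @param volumes Tumor volumes in cc (ascending). Default: the sixteen
#'   reference volumes when `n_patients == 16`, otherwise sampled uniformly
#'   from `volume_range`.
#' @param volume_range Sampling range for tumor volumes (cc).
#' @param shape_factor Maximal-diameter to equivalent-sphere-diameter ratio
#'   (default 1.1; tumors are not perfect spheres).
#' @param grid Relative-dose grid resolution (default 0.005, i.e. about
#'   5 cGy per 10 Gy of prescription).
#' @param hotspot_range Range of the GTV maximum relative dose.
#' @param gtv_ramp_range Range of the GTV dose-falloff exponent (smaller
#'   values concentrate volume near the hotspot).
#' @param lung_k0 Base lung tail scale; the per-patient scale is
#'   `lung_k0 * (tumor_volume / lung_volume)^(1/3)` times a jitter factor.
#' @param lung_jitter_range Multiplicative jitter for the lung tail scale.
#' @param lung_volume_range Lung volumes (cc) for ordinary patients.
#' @param small_r_lung_range Lung volumes (cc) for the low-R quarter.
#' @param r_threshold R value separating the lung strata (default 400).
#' @param cw_volume Chest-wall band volume in cc (default 300).
#' @param cw_lambda Chest-wall dose decay length in mm (default 20).
#' @param cw_tau_frac Chest-wall DVH falloff scale as a fraction of the peak
#'   relative dose (default 0.45).
#' @param cw_tau_jitter_range Multiplicative jitter for `cw_tau_frac`.
#' @param d_near,d_mid,d_far Tumor-to-chest-wall distance ranges (mm) for the
#'   three distance bands.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16, seed = 1, volumes = NULL,
                        volume_range = c(0.9, 11.6), shape_factor = 1.1,
                        grid = 0.005,
                        hotspot_range = c(1.20, 1.30),
                        gtv_ramp_range = c(0.3, 0.55),
                        lung_k0 = 0.9,
                        lung_jitter_range = c(0.92, 1.08),
                        lung_volume_range = c(2600, 4200),
                        small_r_lung_range = c(1900, 2700),
                        r_threshold = 400,
                        cw_volume = 300, cw_lambda = 20,
                        cw_tau_frac = 0.45,
                        cw_tau_jitter_range = c(0.9, 1.1),
                        d_near = c(1, 5.4), d_mid = c(6, 14),
                        d_far = c(15, 35)) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be >= 1")
  }
  if (!is.null(volumes)) {
    volumes <- sort(as.numeric(volumes))
    if (length(volumes) != n_patients) {
      stop("volumes must have length n_patients")
    }
    if (any(volumes <= 0)) stop("tumor volumes must be > 0")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      volumes = volumes, volume_range = volume_range,
      shape_factor = shape_factor, grid = grid,
      hotspot_range = hotspot_range, gtv_ramp_range = gtv_ramp_range,
      lung_k0 = lung_k0, lung_jitter_range = lung_jitter_range,
      lung_volume_range = lung_volume_range,
      small_r_lung_range = small_r_lung_range,
      r_threshold = r_threshold,
      cw_volume = cw_volume, cw_lambda = cw_lambda,
      cw_tau_frac = cw_tau_frac,
      cw_tau_jitter_range = cw_tau_jitter_range,
      d_near = d_near, d_mid = d_mid, d_far = d_far
    ),
    class = "cohort_spec"
  )
}

# the sixteen reference GTV volumes (cc), ascending
.reference_volumes <- c(0.9, 1.0, 2.1, 3.1, 3.3, 3.4, 3.6, 4.0, 4.2, 4.2,
                        4.6, 5.4, 6.9, 9.7, 10.3, 11.6)

#' Synthetic GTV differential DVH (relative dose)
#'
#' Builds a GTV dose distribution in units of the prescription dose: the
#' whole volume receives at least relative dose 1.0 and the maximum is
#' `hotspot_level` (must lie in 1.20-1.30). The cumulative volume falls off
#' as `((h - x)/(h - 1))^p` between 1 and the hotspot `h`; the ramp exponent
#' `p` < 1 concentrates volume near the hotspot, as in plans normalized for
#' 95% prescription coverage of the surrounding PTV.
#'
#' @param tumor_volume GTV volume in cc (> 0).
#' @param hotspot_level Maximum relative dose, in `[1.20, 1.30]`.
#' @param ramp_exponent Falloff exponent `p`; `NULL` draws it uniformly from
#'   `ramp_range` using the current RNG state.
#' @param ramp_range Range for the drawn exponent.
#' @param grid Relative-dose grid width.
#' @param seed Optional seed set before drawing jittered parameters.
#' @return A relative-dose [ddvh()].
#' @export
make_gtv_dvh <- function(tumor_volume, hotspot_level, ramp_exponent = NULL,
                         ramp_range = c(0.3, 0.55), grid = 0.005,
                         seed = NULL) {
  stopifnot(tumor_volume > 0)
  if (hotspot_level < 1.20 || hotspot_level > 1.30) {
    stop("hotspot_level must lie in [1.20, 1.30]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ramp_exponent)) {
    ramp_exponent <- stats::runif(1, ramp_range[1L], ramp_range[2L])
  }
  h <- hotspot_level
  edges <- unique(c(seq(0, h, by = grid), h))
  vol <- ifelse(
    edges <= 1, tumor_volume,
    tumor_volume * ((h - edges) / (h - 1))^ramp_exponent
  )
  cd <- cdvh(edges, vol, structure = "GTV", scale = "relative")
  .drop_empty_bins(cumulative_to_differential(cd))
}

#' Synthetic lung differential DVH (relative dose)
#'
#' Exponential-tail lung dose distribution: the cumulative volume at
#' relative dose x is `lung_volume * exp(-x / k)` with tail scale
#' `k = k0 * (tumor_volume / lung_volume)^(1/3) * k_jitter`, so the mean
#' relative lung dose decreases as the lung-to-tumor volume ratio R grows.
#'
#' @param lung_volume Lung volume in cc (> tumor volume).
#' @param tumor_volume Tumor volume in cc (> 0).
#' @param k0 Base tail scale (default 0.9).
#' @param k_jitter Multiplicative jitter; `NULL` draws from `jitter_range`.
#' @param jitter_range Jitter range.
#' @param grid Relative-dose grid width.
#' @param seed Optional seed.
#' @return A relative-dose [ddvh()].
#' @export
make_lung_dvh <- function(lung_volume, tumor_volume, k0 = 0.9,
                          k_jitter = NULL, jitter_range = c(0.92, 1.08),
                          grid = 0.005, seed = NULL) {
  if (!is.numeric(lung_volume) || !is.numeric(tumor_volume) ||
      tumor_volume <= 0 || lung_volume <= tumor_volume) {
    stop("need lung_volume > tumor_volume > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k_jitter)) {
    k_jitter <- stats::runif(1, jitter_range[1L], jitter_range[2L])
  }
  k <- k0 * (tumor_volume / lung_volume)^(1 / 3) * k_jitter
  n <- ceiling(k * log(1e9) / grid)
  edges <- c(0, seq_len(n)) * grid
  vol <- lung_volume * exp(-edges / k)
  cd <- cdvh(edges, vol, structure = "Lung", scale = "relative")
  cumulative_to_differential(cd)
}

#' Synthetic chest-wall differential DVH (relative dose)
#'
#' The peak relative chest-wall dose is
#' `hotspot_level * exp(-cw_distance / lambda)` (lambda default 20 mm), so
#' tumors abutting the chest wall expose it to near-target dose while the
#' peak decays with distance. Below the peak the cumulative volume falls off
#' exponentially with scale `tau_frac * peak`; the band volume (default
#' 300 cc) is conserved.
#'
#' @param cw_volume Chest-wall band volume in cc.
#' @param cw_distance Tumor-to-chest-wall distance in mm (>= 0).
#' @param hotspot_level Plan maximum relative dose.
#' @param lambda Decay length in mm (default 20).
#' @param tau_frac Falloff scale as a fraction of the peak dose.
#' @param tau_jitter Multiplicative jitter; `NULL` draws from `jitter_range`.
#' @param jitter_range Jitter range.
#' @param grid Relative-dose grid width.
#' @param seed Optional seed.
#' @return A relative-dose [ddvh()].
#' @export
make_cw_dvh <- function(cw_volume = 300, cw_distance, hotspot_level,
                        lambda = 20, tau_frac = 0.45, tau_jitter = NULL,
                        jitter_range = c(0.9, 1.1), grid = 0.005,
                        seed = NULL) {
  if (!is.numeric(cw_distance) || cw_distance < 0) {
    stop("cw_distance must be >= 0")
  }
  stopifnot(cw_volume > 0, hotspot_level > 0, lambda > 0, tau_frac > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tau_jitter)) {
    tau_jitter <- stats::runif(1, jitter_range[1L], jitter_range[2L])
  }
  peak <- hotspot_level * exp(-cw_distance / lambda)
  tau <- tau_frac * peak * tau_jitter
  edges <- unique(c(seq(0, peak, by = grid), peak))
  vol <- cw_volume * exp(-edges / tau)
  cd <- cdvh(edges, vol, structure = "ChestWall", scale = "relative")
  cumulative_to_differential(cd)
}

#' Generate a synthetic patient cohort
#'
#' Produces `spec$n_patients` patient plans, each holding relative-dose
#' GTV/lung/chest-wall differential DVHs plus tumor geometry (volume,
#' maximal diameter, lung volume, lung-to-tumor ratio R, chest-wall distance
#' D). The result is a pure function of the spec, including its seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `patient_cohort` of `patient_plan` objects.
#' @seealso [cohort_manifest()], [scale_to_scheme()]
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  vols <- spec$volumes
  if (is.null(vols)) {
    vols <- if (n == 16L) .reference_volumes else {
      sort(stats::runif(n, spec$volume_range[1L], spec$volume_range[2L]))
    }
  }
  # deterministic stratum assignment (ascending volume order)
  n_low <- if (n >= 4L) max(1L, round(n / 4)) else 0L
  strata <- character(n)
  if (n_low > 0L) strata[(n - n_low + 1L):n] <- "low_r"
  rest <- which(strata == "")
  strata[rest] <- rep(c("near", "mid", "far"), length.out = length(rest))

  plans <- vector("list", n)
  for (i in seq_len(n)) {
    v <- vols[i]
    if (strata[i] == "low_r") {
      lung <- stats::runif(1, spec$small_r_lung_range[1L],
                           spec$small_r_lung_range[2L])
      lung <- min(lung, 0.98 * spec$r_threshold * v)  # keep R below threshold
      lung <- max(lung, 2 * v)
      d <- stats::runif(1, spec$d_far[1L], spec$d_far[2L])
    } else {
      lung <- stats::runif(1, spec$lung_volume_range[1L],
                           spec$lung_volume_range[2L])
      lung <- max(lung, 1.02 * spec$r_threshold * v)   # keep R above threshold
      rng <- switch(strata[i], near = spec$d_near, mid = spec$d_mid,
                    far = spec$d_far)
      d <- stats::runif(1, rng[1L], rng[2L])
    }
    hotspot <- stats::runif(1, spec$hotspot_range[1L], spec$hotspot_range[2L])
    ramp <- stats::runif(1, spec$gtv_ramp_range[1L], spec$gtv_ramp_range[2L])
    kj <- stats::runif(1, spec$lung_jitter_range[1L],
                       spec$lung_jitter_range[2L])
    tj <- stats::runif(1, spec$cw_tau_jitter_range[1L],
                       spec$cw_tau_jitter_range[2L])
    plans[[i]] <- structure(
      list(
        patient_id = sprintf("P%02d", i),
        gtv_ddvh = make_gtv_dvh(v, hotspot, ramp_exponent = ramp,
                                grid = spec$grid),
        lung_ddvh = make_lung_dvh(lung, v, k0 = spec$lung_k0,
                                  k_jitter = kj, grid = spec$grid),
        cw_ddvh = make_cw_dvh(spec$cw_volume, d, hotspot,
                              lambda = spec$cw_lambda,
                              tau_frac = spec$cw_tau_frac, tau_jitter = tj,
                              grid = spec$grid),
        tumor_volume = v,
        tumor_diameter = spec$shape_factor * (6 * v / pi)^(1 / 3),
        lung_volume = lung,
        r_ratio = lung / v,
        cw_distance = d,
        dose_scale = "relative"
      ),
      class = "patient_plan"
    )
  }
  structure(plans, class = "patient_cohort")
}

#' @export
print.patient_plan <- function(x, ...) {
  cat(sprintf(
    "Patient %s: GTV %.1f cc (diam %.2f cm), lung %.0f cc (R = %.0f), CW distance %.1f mm [%s dose]\n",
    x$patient_id, x$tumor_volume, x$tumor_diameter, x$lung_volume,
    x$r_ratio, x$cw_distance, x$dose_scale
  ))
  invisible(x)
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort of %d patients\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort A `patient_cohort` from [generate_cohort()].
#' @return A data.frame with patient_id, tumor_volume, tumor_diameter,
#'   lung_volume, r_ratio and cw_distance.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "patient_cohort"))
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      patient_id = p$patient_id, tumor_volume = p$tumor_volume,
      tumor_diameter = p$tumor_diameter, lung_volume = p$lung_volume,
      r_ratio = p$r_ratio, cw_distance = p$cw_distance,
      stringsAsFactors = FALSE
    )
  }))
}

#' Scale a relative-dose plan to a fraction scheme
#'
#' Multiplies every bin dose of the patient's three DVHs by the scheme's
#' total prescription dose and tags the plan as physical dose. Volumes are
#' untouched; scaling an already-physical plan is an error.
#'
#' @param plan A `patient_plan` in relative dose.
#' @param scheme A [fraction_scheme()].
#' @return The plan in physical dose (Gy).
#' @export
scale_to_scheme <- function(plan, scheme) {
  stopifnot(inherits(plan, "patient_plan"),
            inherits(scheme, "fraction_scheme"))
  if (plan$dose_scale != "relative") {
    stop("plan is already on the '", plan$dose_scale,
         "' scale; refusing to scale twice")
  }
  total <- scheme$total_dose
  rescale <- function(d) {
    ddvh(d$dose * total, d$volume, total_volume = d$total_volume,
         structure = d$structure, scale = "physical")
  }
  plan$gtv_ddvh <- rescale(plan$gtv_ddvh)
  plan$lung_ddvh <- rescale(plan$lung_ddvh)
  plan$cw_ddvh <- rescale(plan$cw_ddvh)
  plan$dose_scale <- "physical"
  plan
}

#' Write a cumulative DVH as generic CSV
#'
#' Writes `# scale:` and `# structure:` comment lines, a header and the
#' dose/volume rows, readable back with [read_dvh_table()].
#'
#' @param dvh A [cdvh()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "cdvh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# structure: %s", dvh$structure),
    sprintf("# scale: %s", dvh$scale),
    "dose,volume_cc"
  ), con)
  writeLines(sprintf("%.10g,%.10g", dvh$dose, dvh$volume), con)
  invisible(path)
}

#' Write a cohort as DVH CSV files plus manifest
#'
#' One `<patient>_<structure>.csv` per structure (cumulative, relative dose)
#' and a `manifest.csv` with the geometry columns of [cohort_manifest()].
#'
#' @param cohort A `patient_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "patient_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    for (s in c("gtv", "lung", "cw")) {
      cd <- differential_to_cumulative(p[[paste0(s, "_ddvh")]])
      write_dvh_csv(cd, file.path(dir, sprintf("%s_%s.csv", p$patient_id, s)))
    }
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort_manifest(cohort), mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the DVH CSVs and `manifest.csv`.
#' @param bin_width Resampling width used for non-uniform grids on read
#'   (relative dose, default 0.005).
#' @return A `patient_cohort`.
#' @export
read_cohort <- function(dir, bin_width = 0.005) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  plans <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$patient_id[i]
    get_ddvh <- function(s) {
      cd <- read_dvh_table(file.path(dir, sprintf("%s_%s.csv", id, s)),
                           bin_width = bin_width)
      cumulative_to_differential(cd)
    }
    gtv <- get_ddvh("gtv")
    structure(
      list(
        patient_id = id,
        gtv_ddvh = gtv, lung_ddvh = get_ddvh("lung"),
        cw_ddvh = get_ddvh("cw"),
        tumor_volume = man$tumor_volume[i],
        tumor_diameter = man$tumor_diameter[i],
        lung_volume = man$lung_volume[i],
        r_ratio = man$r_ratio[i],
        cw_distance = man$cw_distance[i],
        dose_scale = gtv$scale
      ),
      class = "patient_plan"
    )
  })
  structure(plans, class = "patient_cohort")
}
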