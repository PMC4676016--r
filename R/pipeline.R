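#' Evaluate every fraction scheme on every patient
#'
#' For each patient and scheme the plan is scaled to the scheme's total
#' prescription dose and all TCP and toxicity models are evaluated. The
#' result holds the long-format entry table, a scheme table with BED10, and
#' per-scheme mean/SD summaries per metric.
#'
#' @param cohort A `patient_cohort` (relative dose) from [generate_cohort()]
#'   or [read_cohort()].
#' @param schemes A list of [fraction_scheme()]s (default: the ten studied
#'   schemes).
#' @param params A [default_model_params()] bundle.
#' @param alpha_betas An [alpha_beta_set()].
#' @return A list of class `cohort_result` with elements
#'   `entries` (data.frame: patient_id, scheme, metric, value),
#'   `schemes` (data.frame: scheme, n_fractions, dose_per_fraction,
#'   total_dose, bed10) and `summary` (data.frame: scheme, metric, mean, sd).
#' @export
evaluate_cohort <- function(cohort, schemes = default_schemes(),
                            params = default_model_params(),
                            alpha_betas = alpha_beta_set()) {
  stopifnot(inherits(cohort, "patient_cohort"), length(cohort) > 0,
            length(schemes) > 0)
  if (is.null(params$fenwick_ntcp)) {
    message("Fenwick lung-NTCP parameters not configured; model skipped, ",
            "lung NTCP median taken over the LKB model only")
  }
  rows <- vector("list", length(cohort) * length(schemes))
  idx <- 0L
  for (plan in cohort) {
    for (scheme in schemes) {
      sp <- scale_to_scheme(plan, scheme)
      tcp <- tcp_all(sp$gtv_ddvh, scheme, sp$tumor_volume,
                     sp$tumor_diameter, params, alpha_betas$tumor)
      tox <- toxicity_all(sp$lung_ddvh, sp$cw_ddvh, scheme, alpha_betas,
                          params, quiet = TRUE)
      vals <- c(
        tcp_martel = unname(tcp$per_model["martel"]),
        tcp_fenwick = unname(tcp$per_model["fenwick"]),
        tcp_webb_nahum = unname(tcp$per_model["webb_nahum"]),
        tcp_eud = unname(tcp$per_model["eud"]),
        tcp_nitin = unname(tcp$per_model["nitin"]),
        tcp_median = tcp$median_tcp,
        ntcp_lkb = tox$lkb_ntcp,
        ntcp_fenwick = tox$fenwick_ntcp,
        ntcp_lung_median = tox$median_lung_ntcp,
        cw_meud = tox$cw_meud
      )
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        patient_id = plan$patient_id, scheme = scheme$label,
        metric = names(vals), value = unname(vals),
        stringsAsFactors = FALSE
      )
    }
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  as_cohort_result(entries, schemes)
}

#' Assemble a cohort result from a long entry table
#'
#' Builds the `cohort_result` container (entries, analytic scheme table and
#' per-scheme mean/SD summary) from a long-format entry data.frame, e.g. one
#' re-read from a `results_long.csv` written by [write_report()].
#'
#' @param entries Data.frame with columns patient_id, scheme, metric, value.
#' @param schemes List of [fraction_scheme()]s covering every scheme label
#'   in `entries`.
#' @return A `cohort_result`, see [evaluate_cohort()].
#' @export
as_cohort_result <- function(entries, schemes = default_schemes()) {
  need <- c("patient_id", "scheme", "metric", "value")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns ", paste(need, collapse = ", "))
  }
  labels <- vapply(schemes, `[[`, "", "label")
  missing <- setdiff(unique(entries$scheme), labels)
  if (length(missing)) {
    stop("no fraction_scheme supplied for: ", paste(missing, collapse = ", "))
  }
  schemes <- schemes[labels %in% unique(entries$scheme)]
  scheme_tab <- do.call(rbind, lapply(schemes, function(s) {
    data.frame(
      scheme = s$label, n_fractions = s$n_fractions,
      dose_per_fraction = s$dose_per_fraction, total_dose = s$total_dose,
      bed10 = bed(s, 10), stringsAsFactors = FALSE
    )
  }))
  rownames(scheme_tab) <- NULL
  agg_mean <- stats::aggregate(value ~ scheme + metric, entries, mean)
  agg_sd <- stats::aggregate(value ~ scheme + metric, entries,
                             function(x) stats::sd(x))
  summary <- merge(agg_mean, agg_sd, by = c("scheme", "metric"),
                   suffixes = c(".mean", ".sd"))
  names(summary) <- c("scheme", "metric", "mean", "sd")
  summary$sd[is.na(summary$sd)] <- 0   # single-patient cohorts
  summary <- summary[order(summary$metric, summary$scheme), ]
  rownames(summary) <- NULL
  structure(
    list(entries = entries, schemes = scheme_tab, summary = summary),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "Cohort result: %d patients x %d schemes x %d metrics\n",
    length(unique(x$entries$patient_id)), nrow(x$schemes),
    length(unique(x$entries$metric))
  ))
  invisible(x)
}

#' Pairwise paired Wilcoxon signed-rank tests across schemes
#'
#' For every pair of schemes, tests the per-patient paired differences of the
#' chosen metric with the two-sided Wilcoxon signed-rank test. Zero
#' differences are dropped (standard signed-rank convention) and the exact
#' null distribution is used for up to 25 nonzero pairs without ties; a pair
#' with no nonzero differences reports p = 1 with a warning.
#'
#' @param result A `cohort_result`.
#' @param metric Metric name (e.g. `"tcp_median"`, `"ntcp_lung_median"`,
#'   `"cw_meud"`).
#' @return A data.frame with scheme_a, scheme_b and p_value, one row per
#'   unordered pair.
#' @export
wilcoxon_pairwise <- function(result, metric = "tcp_median") {
  stopifnot(inherits(result, "cohort_result"))
  e <- result$entries[result$entries$metric == metric, ]
  if (nrow(e) == 0L) stop("unknown metric: ", metric)
  wide <- stats::reshape(
    e[, c("patient_id", "scheme", "value")],
    idvar = "patient_id", timevar = "scheme", direction = "wide"
  )
  labels <- sub("^value\\.", "", names(wide)[-1L])
  if (length(labels) < 2L) stop("need at least two schemes")
  pairs <- utils::combn(seq_along(labels), 2L)
  out <- data.frame(
    scheme_a = labels[pairs[1L, ]], scheme_b = labels[pairs[2L, ]],
    p_value = NA_real_, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    d <- wide[[pairs[1L, j] + 1L]] - wide[[pairs[2L, j] + 1L]]
    d <- d[d != 0]
    if (length(d) == 0L) {
      warning("all paired differences are zero for ", out$scheme_a[j], " vs ",
              out$scheme_b[j], "; p = 1")
      out$p_value[j] <- 1
    } else {
      exact <- length(d) <= 25L
      out$p_value[j] <- suppressWarnings(
        stats::wilcox.test(d, exact = exact)$p.value
      )
    }
  }
  out
}

#' Stratified toxicity summary
#'
#' Splits the cohort into the lung risk strata (R <= `r_threshold` with
#' chest-wall distance D >= `d_lung` mm, versus the complement) and the
#' chest-wall strata (D <= `d_cw` mm versus larger), and reports mean and SD
#' of the median lung NTCP and of the chest-wall mEUD per scheme and
#' stratum. Empty strata are absent from the output rather than reported as
#' NaN.
#'
#' @param result A `cohort_result`.
#' @param manifest Cohort manifest data.frame (see [cohort_manifest()]) with
#'   `r_ratio` and `cw_distance` per patient.
#' @param r_threshold Lung-to-tumor volume ratio threshold (default 400).
#' @param d_lung Chest-wall distance threshold of the lung strata, mm
#'   (default 15).
#' @param d_cw Chest-wall distance threshold of the chest-wall strata, mm
#'   (default 5.5).
#' @return A list of class `stratified_summary` with data.frames `lung`
#'   (scheme, stratum, n, mean, sd of median lung NTCP) and `chest_wall`
#'   (same for mEUD), plus the stratum labels per patient in `assignment`.
#' @export
stratify <- function(result, manifest, r_threshold = 400, d_lung = 15,
                     d_cw = 5.5) {
  stopifnot(inherits(result, "cohort_result"))
  need <- c("patient_id", "r_ratio", "cw_distance")
  if (!all(need %in% names(manifest))) {
    stop("manifest must provide ", paste(need, collapse = ", "))
  }
  man <- manifest
  man$lung_stratum <- ifelse(
    man$r_ratio <= r_threshold & man$cw_distance >= d_lung,
    "highrisk", "lowrisk"
  )
  man$cw_stratum <- ifelse(man$cw_distance <= d_cw, "near", "far")
  summarize <- function(metric, stratum_col) {
    e <- result$entries[result$entries$metric == metric, ]
    e <- merge(e, man[, c("patient_id", stratum_col)], by = "patient_id")
    names(e)[names(e) == stratum_col] <- "stratum"
    agg <- stats::aggregate(
      value ~ scheme + stratum, e,
      function(x) c(n = length(x), mean = mean(x),
                    sd = if (length(x) > 1) stats::sd(x) else 0)
    )
    out <- data.frame(
      scheme = agg$scheme, stratum = agg$stratum,
      n = agg$value[, "n"], mean = agg$value[, "mean"],
      sd = agg$value[, "sd"], stringsAsFactors = FALSE
    )
    out[order(out$stratum, out$scheme), ]
  }
  lung <- summarize("ntcp_lung_median", "lung_stratum")
  cw <- summarize("cw_meud", "cw_stratum")
  rownames(lung) <- rownames(cw) <- NULL
  structure(
    list(
      lung = lung, chest_wall = cw,
      assignment = man[, c("patient_id", "lung_stratum", "cw_stratum")],
      thresholds = c(r = r_threshold, d_lung = d_lung, d_cw = d_cw)
    ),
    class = "stratified_summary"
  )
}

#' Optimal fraction scheme per risk scenario
#'
#' Applies the decision rule: among schemes whose cohort-mean median-model
#' TCP is at least that of the reference scheme and whose stratum-mean lung
#' NTCP and chest-wall mEUD stay within the configured tolerances of the
#' reference, recommend the scheme with the fewest fractions (ties broken by
#' higher TCP). Two scenarios are assessed: `favorable` (large
#' lung-to-tumor ratio or mid-range chest-wall distance; lung NTCP from the
#' low-risk lung stratum, mEUD from the far chest-wall stratum) and
#' `unfavorable` (small R with distant chest wall, or tumor abutting the
#' chest wall; high-risk lung stratum and near chest-wall stratum). If no
#' scheme qualifies in a scenario the reference scheme is returned with an
#' explanation.
#'
#' @param result A `cohort_result`.
#' @param strata A [stratify()] summary.
#' @param reference Reference scheme label (default `"4x12"`).
#' @param ntcp_margin Absolute NTCP tolerance (probability, default 0.03 =
#'   3 percentage points).
#' @param meud_margin Relative mEUD tolerance (default 0.35 = 35%).
#' @return A data.frame of class `fs_recommendation`: scenario,
#'   recommended_scheme, reference_scheme, n_fractions, tcp_delta,
#'   ntcp_delta, meud_ratio, rationale.
#' @export
recommend <- function(result, strata, reference = "4x12",
                      ntcp_margin = 0.03, meud_margin = 0.35) {
  stopifnot(inherits(result, "cohort_result"),
            inherits(strata, "stratified_summary"))
  if (!reference %in% result$schemes$scheme) {
    stop("reference scheme '", reference, "' not in the result")
  }
  tcp <- result$summary[result$summary$metric == "tcp_median", ]
  tcp_of <- function(s) tcp$mean[tcp$scheme == s]
  scen <- list(
    favorable = c(lung = "lowrisk", cw = "far"),
    unfavorable = c(lung = "highrisk", cw = "near")
  )
  sch <- result$schemes[order(result$schemes$scheme), ]
  out <- NULL
  for (name in names(scen)) {
    lt <- strata$lung[strata$lung$stratum == scen[[name]]["lung"], ]
    ct <- strata$chest_wall[strata$chest_wall$stratum == scen[[name]]["cw"], ]
    if (nrow(lt) == 0L || nrow(ct) == 0L) {
      out <- rbind(out, data.frame(
        scenario = name, recommended_scheme = reference,
        reference_scheme = reference,
        n_fractions = sch$n_fractions[sch$scheme == reference],
        tcp_delta = 0, ntcp_delta = 0, meud_ratio = 1,
        rationale = "stratum empty; defaulting to the reference scheme",
        stringsAsFactors = FALSE
      ))
      next
    }
    ntcp_of <- function(s) lt$mean[lt$scheme == s]
    meud_of <- function(s) ct$mean[ct$scheme == s]
    ref_tcp <- tcp_of(reference)
    ref_ntcp <- ntcp_of(reference)
    ref_meud <- meud_of(reference)
    cand <- sch
    cand$tcp <- vapply(cand$scheme, tcp_of, 0)
    cand$ntcp <- vapply(cand$scheme, ntcp_of, 0)
    cand$meud <- vapply(cand$scheme, meud_of, 0)
    eps <- 1e-12
    ok <- cand$tcp >= ref_tcp - eps &
      cand$ntcp <= ref_ntcp + ntcp_margin + eps &
      cand$meud <= ref_meud * (1 + meud_margin) + eps
    qual <- cand[ok, ]
    if (nrow(qual) == 0L) {
      pick <- cand[cand$scheme == reference, ]
      rationale <- "no scheme met the tolerances; reference retained"
    } else {
      qual <- qual[order(qual$n_fractions, -qual$tcp, qual$scheme), ]
      pick <- qual[1L, ]
      rationale <- sprintf(
        "fewest fractions (%d) among %d qualifying schemes; TCP %+.1f pp, lung NTCP %+.1f pp, CW mEUD x%.2f vs %s",
        pick$n_fractions, nrow(qual), 100 * (pick$tcp - ref_tcp),
        100 * (pick$ntcp - ref_ntcp), pick$meud / ref_meud, reference
      )
    }
    out <- rbind(out, data.frame(
      scenario = name, recommended_scheme = pick$scheme,
      reference_scheme = reference, n_fractions = pick$n_fractions,
      tcp_delta = pick$tcp - ref_tcp, ntcp_delta = pick$ntcp - ref_ntcp,
      meud_ratio = pick$meud / ref_meud, rationale = rationale,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  class(out) <- c("fs_recommendation", "data.frame")
  out
}

.fmt_pct <- function(mean, sd) sprintf("%.1f ± %.1f", 100 * mean, 100 * sd)
.fmt_gy <- function(mean, sd) sprintf("%.1f ± %.1f", mean, sd)

#' Write the analysis report
#'
#' Writes the per-patient long-format results, a scheme-by-metric summary
#' table (mean ± SD, percentages to one decimal), the stratified toxicity
#' tables and the recommendations as CSV, plus a machine-readable JSON
#' summary. Regenerating the report from the same result is byte-identical.
#'
#' @param result A `cohort_result`.
#' @param strata A [stratify()] summary.
#' @param recommendations A [recommend()] table.
#' @param dir Output directory (created if needed).
#' @param plots Also write an EQD2 cumulative-DVH plot per structure for the
#'   supplied `cohort` (PDF; optional).
#' @param cohort Cohort used for the plots (first patient shown).
#' @param schemes Schemes used for the plots.
#' @param alpha_betas Alpha/beta set for the plots.
#' @return Invisibly, the output directory.
#' @export
write_report <- function(result, strata, recommendations, dir,
                         plots = FALSE, cohort = NULL,
                         schemes = default_schemes(),
                         alpha_betas = alpha_beta_set()) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$entries, file.path(dir, "results_long.csv"),
                   row.names = FALSE)
  # scheme-by-metric summary in the style of the main comparison table
  s <- result$summary
  metrics <- unique(s$metric)
  wide <- data.frame(metric = c("bed10", metrics), stringsAsFactors = FALSE)
  for (lab in result$schemes$scheme) {
    col <- c(
      sprintf("%.1f", result$schemes$bed10[result$schemes$scheme == lab]),
      vapply(metrics, function(m) {
        row <- s[s$scheme == lab & s$metric == m, ]
        if (m == "cw_meud") .fmt_gy(row$mean, row$sd)
        else .fmt_pct(row$mean, row$sd)
      }, "")
    )
    wide[[lab]] <- col
  }
  utils::write.csv(wide, file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  utils::write.csv(strata$lung, file.path(dir, "strata_lung.csv"),
                   row.names = FALSE)
  utils::write.csv(strata$chest_wall, file.path(dir, "strata_chest_wall.csv"),
                   row.names = FALSE)
  utils::write.csv(recommendations, file.path(dir, "recommendations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      schemes = result$schemes, summary = result$summary,
      strata = list(lung = strata$lung, chest_wall = strata$chest_wall),
      recommendations = recommendations
    ),
    file.path(dir, "summary.json"),
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  if (plots && !is.null(cohort)) {
    .plot_eqd2_cdvh(cohort, schemes, alpha_betas,
                    file.path(dir, "eqd2_cdvh.pdf"))
  }
  invisible(dir)
}

# EQD2 cumulative DVHs of the first patient, one panel per structure
.plot_eqd2_cdvh <- function(cohort, schemes, alpha_betas, path) {
  grDevices::pdf(path, width = 9, height = 3.2)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  plan <- cohort[[1L]]
  cols <- grDevices::hcl.colors(length(schemes), "Dark 3")
  for (s in c("gtv", "lung", "cw")) {
    ab <- switch(s, gtv = alpha_betas$tumor, lung = alpha_betas$lung,
                 cw = alpha_betas$chest_wall)
    first <- TRUE
    for (j in seq_along(schemes)) {
      sp <- scale_to_scheme(plan, schemes[[j]])
      eq <- convert_ddvh(sp[[paste0(s, "_ddvh")]], schemes[[j]], ab, "EQD2")
      cd <- differential_to_cumulative(eq)
      plot(cd, add = !first, col = cols[j])
      first <- FALSE
    }
    graphics::legend("topright", legend = names(schemes), col = cols,
                     lwd = 1, cex = 0.5, bty = "n")
  }
  invisible(path)
}
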