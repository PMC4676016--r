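#' Cumulative dose-volume histogram
#'
#' A cumulative DVH (cDVH) stores, for each dose edge, the absolute volume
#' (cc) of the structure receiving at least that dose. This is the format
#' planning systems export; all outcome models in this package operate on the
#' differential form obtained with [cumulative_to_differential()].
#'
#' Each DVH carries a `scale` tag (`"physical"`, `"relative"`, `"EQD2"` or
#' `"BED"`) so that linear-quadratic conversions cannot be applied twice.
#'
#' @param dose Numeric vector of dose edges (Gy, or relative dose when
#'   `scale = "relative"`), strictly increasing, first edge usually 0.
#' @param volume Numeric vector of volumes at or above each edge (cc),
#'   monotone non-increasing, same length as `dose`.
#' @param structure Structure label (e.g. `"GTV"`).
#' @param scale Dose-scale tag.
#' @return An object of class `cdvh` with fields `dose`, `volume`,
#'   `total_volume`, `structure`, `scale`.
#' @seealso [ddvh()], [read_dvh_table()], [resample_cumulative()]
#' @examples
#' cv <- cdvh(c(0, 24, 48, 60), c(10, 10, 6, 0), structure = "GTV")
#' cv$total_volume
#' @export
cdvh <- function(dose, volume, structure = "", scale = "physical") {
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) == 0L) stop("empty DVH table")
  if (length(dose) != length(volume)) {
    stop("dose and volume must have the same length")
  }
  if (anyNA(dose) || anyNA(volume)) stop("DVH contains missing values")
  if (any(diff(dose) <= 0)) stop("dose edges must be strictly increasing")
  if (dose[1L] < 0) stop("negative dose edge")
  if (any(volume < 0)) stop("negative volume")
  if (any(diff(volume) > 0)) {
    stop("cumulative volume must be monotone non-increasing in dose")
  }
  scale <- match.arg(scale, c("physical", "relative", "EQD2", "BED"))
  structure(
    list(
      dose = dose, volume = volume,
      total_volume = volume[1L],
      structure = as.character(structure)[1L],
      scale = scale
    ),
    class = "cdvh"
  )
}

#' Differential dose-volume histogram
#'
#' A differential DVH (dDVH) stores the absolute volume `volume[i]` (cc)
#' receiving the bin-representative dose `dose[i]`. Bin volumes sum to the
#' structure's total volume; this is the per-bin (D_i, V_i) currency consumed
#' by the TCP and NTCP models.
#'
#' @param dose Bin-representative doses (Gy), non-negative.
#' @param volume Bin volumes (cc), non-negative.
#' @param total_volume Total structure volume; defaults to `sum(volume)` and
#'   must agree with it to 1e-9 relative tolerance.
#' @param structure Structure label.
#' @param scale Dose-scale tag, see [cdvh()].
#' @return An object of class `ddvh`.
#' @export
ddvh <- function(dose, volume, total_volume = sum(volume), structure = "",
                 scale = "physical") {
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) == 0L) stop("empty DVH")
  if (length(dose) != length(volume)) {
    stop("dose and volume must have the same length")
  }
  if (anyNA(dose) || anyNA(volume)) stop("DVH contains missing values")
  if (any(dose < 0)) stop("negative bin dose")
  if (any(volume < 0)) stop("negative bin volume")
  if (total_volume > 0 &&
      abs(sum(volume) - total_volume) > 1e-9 * total_volume) {
    stop("bin volumes do not sum to total_volume")
  }
  scale <- match.arg(scale, c("physical", "relative", "EQD2", "BED"))
  structure(
    list(
      dose = dose, volume = volume,
      total_volume = total_volume,
      structure = as.character(structure)[1L],
      scale = scale
    ),
    class = "ddvh"
  )
}

#' @export
print.cdvh <- function(x, ...) {
  cat(sprintf(
    "Cumulative DVH%s: %d edges, %.4g cc, dose %.4g-%.4g (%s)\n",
    if (nzchar(x$structure)) paste0(" [", x$structure, "]") else "",
    length(x$dose), x$total_volume, min(x$dose), max(x$dose), x$scale
  ))
  invisible(x)
}

#' @export
print.ddvh <- function(x, ...) {
  cat(sprintf(
    "Differential DVH%s: %d bins, %.4g cc, dose %.4g-%.4g (%s)\n",
    if (nzchar(x$structure)) paste0(" [", x$structure, "]") else "",
    length(x$dose), x$total_volume, min(x$dose), max(x$dose), x$scale
  ))
  invisible(x)
}

#' Read a DVH table from disk
#'
#' Reads a cumulative DVH from either a generic two-column CSV (dose in Gy
#' ascending, absolute volume in cc; `#` comment lines ignored, header row
#' optional) or a block-structured planning-system text export with a
#' `Structure:` header and a whitespace-separated dose/volume table. In the
#' export dialect a relative-volume column (percent) is converted to absolute
#' volume using the `Total Volume:` header line.
#'
#' A non-monotone volume column is an error, never silently sorted. Inputs on
#' a non-uniform dose grid are resampled onto a uniform grid of width
#' `bin_width` on read.
#'
#' @param path Path to the file.
#' @param dialect `"generic_csv"` or `"export_text"`.
#' @param structure For `export_text` files with several blocks, the name of
#'   the structure block to read (default: first block).
#' @param bin_width Grid width used when the input grid is non-uniform
#'   (default 0.05 Gy, the usual 5 cGy export resolution).
#' @return A [cdvh()].
#' @export
read_dvh_table <- function(path, dialect = c("generic_csv", "export_text"),
                           structure = NULL, bin_width = 0.05) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "generic_csv") {
    lines <- readLines(path, warn = FALSE)
    scale <- .parse_scale_comment(lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("empty DVH table: ", path)
    # drop a single header row if its fields are not numeric
    first <- strsplit(lines[1L], ",")[[1L]]
    if (anyNA(suppressWarnings(as.numeric(first)))) lines <- lines[-1L]
    if (length(lines) == 0L) stop("empty DVH table: ", path)
    fields <- strsplit(lines, ",")
    if (any(lengths(fields) < 2L)) stop("expected two columns in ", path)
    dose <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    vol <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(dose) || anyNA(vol)) stop("non-numeric DVH rows in ", path)
    label <- if (is.null(structure)) "" else structure
    out <- cdvh(dose, vol, structure = label, scale = scale)
  } else {
    out <- .read_export_text(path, structure)
  }
  if (!.is_uniform_grid(out$dose)) {
    out <- resample_cumulative(out, bin_width)
  }
  out
}

.parse_scale_comment <- function(lines) {
  m <- grep("^#\\s*scale\\s*:", lines, value = TRUE)
  if (length(m) == 0L) return("physical")
  sc <- trimws(sub("^#\\s*scale\\s*:", "", m[1L]))
  if (sc %in% c("physical", "relative", "EQD2", "BED")) sc else "physical"
}

.is_uniform_grid <- function(x) {
  if (length(x) < 3L) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1L])) <= 1e-9 * max(d)
}

# Planning-system export dialect: one or more blocks of the form
#   Structure: <name>
#   Total Volume: <cc> cc        (optional; required for relative volumes)
#   <dose> <volume>              (whitespace separated; volume in cc or %)
.read_export_text <- function(path, structure = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- grep("^Structure\\s*:", lines)
  if (length(starts) == 0L) stop("no 'Structure:' block in ", path)
  names <- trimws(sub("^Structure\\s*:", "", lines[starts]))
  idx <- if (is.null(structure)) 1L else match(structure, names)
  if (is.na(idx)) stop("structure '", structure, "' not found in ", path)
  from <- starts[idx]
  to <- if (idx < length(starts)) starts[idx + 1L] - 1L else length(lines)
  block <- lines[(from + 1L):to]
  tv <- NA_real_
  tv_line <- grep("^Total\\s*Volume\\s*:", block, value = TRUE)
  if (length(tv_line)) {
    tv <- as.numeric(sub("^Total\\s*Volume\\s*:\\s*([0-9.eE+-]+).*", "\\1",
                         tv_line[1L]))
  }
  rows <- block[grepl("^[0-9.]", block)]
  if (length(rows) == 0L) stop("empty DVH block in ", path)
  mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v)) stop("non-numeric DVH rows in ", path)
    v
  }))
  dose <- mat[, 1L]
  vol <- mat[, 2L]
  relative <- grepl("%", rows[1L]) ||
    (!is.na(tv) && abs(vol[1L] - 100) < 1e-6 && tv != 100)
  if (relative) {
    if (is.na(tv)) stop("relative-volume block without 'Total Volume:' header")
    vol <- vol / 100 * tv
  }
  cdvh(dose, vol, structure = names[idx])
}

#' Resample a cumulative DVH onto a uniform dose grid
#'
#' Linearly interpolates the volume-at-or-above curve onto a uniform grid from
#' 0 to the maximum dose (inclusive). The total volume is preserved exactly.
#'
#' @param dvh A [cdvh()].
#' @param bin_width Grid width in Gy (> 0); default 0.05 (5 cGy).
#' @return A [cdvh()] on the uniform grid.
#' @export
resample_cumulative <- function(dvh, bin_width = 0.05) {
  stopifnot(inherits(dvh, "cdvh"))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  dmax <- max(dvh$dose)
  n <- ceiling(dmax / bin_width - 1e-12)
  grid <- c(0, seq_len(n)) * bin_width
  xs <- dvh$dose
  ys <- dvh$volume
  if (xs[1L] > 0) {            # cumulative volume is flat below the first edge
    xs <- c(0, xs)
    ys <- c(dvh$total_volume, ys)
  }
  vol <- stats::approx(
    x = xs, y = ys, xout = grid, method = "linear", rule = 2,
    ties = "ordered"
  )$y
  # guard against interpolation round-off breaking monotonicity
  vol <- rev(cummax(rev(vol)))
  cdvh(grid, vol, structure = dvh$structure, scale = dvh$scale)
}

#' Convert a cumulative DVH to differential form
#'
#' Differencing of the volume-at-or-above column: bin i holds the volume
#' between consecutive edges at the interval midpoint dose, and the final
#' edge contributes a terminal bin with its residual volume at that edge's
#' dose. Bin volumes sum to the total volume exactly.
#'
#' @param dvh A [cdvh()].
#' @return A [ddvh()] on the same dose scale.
#' @export
cumulative_to_differential <- function(dvh) {
  stopifnot(inherits(dvh, "cdvh"))
  k <- length(dvh$dose)
  if (k == 1L) {
    return(ddvh(dvh$dose, dvh$volume,
                structure = dvh$structure, scale = dvh$scale))
  }
  mids <- (dvh$dose[-k] + dvh$dose[-1L]) / 2
  dv <- -diff(dvh$volume)
  ddvh(
    dose = c(mids, dvh$dose[k]),
    volume = c(dv, dvh$volume[k]),
    total_volume = dvh$total_volume,
    structure = dvh$structure, scale = dvh$scale
  )
}

#' Convert a differential DVH back to cumulative form
#'
#' The cumulative volume at dose D is the sum of all bin volumes with bin
#' dose at or above D. Used for round-trip validation and for plotting
#' EQD2-converted cumulative DVHs.
#'
#' @param ddvh A [ddvh()].
#' @param edges Dose edges at which to evaluate; default 0 plus the sorted
#'   distinct bin doses.
#' @return A [cdvh()].
#' @export
differential_to_cumulative <- function(ddvh, edges = NULL) {
  stopifnot(inherits(ddvh, "ddvh"))
  if (is.null(edges)) {
    edges <- sort(unique(c(0, ddvh$dose)))
  }
  vol <- vapply(edges, function(e) sum(ddvh$volume[ddvh$dose >= e]), 0)
  cdvh(edges, vol, structure = ddvh$structure, scale = ddvh$scale)
}

#' Volume-weighted mean dose of a differential DVH
#'
#' @param ddvh A [ddvh()] with positive total volume.
#' @return Mean dose (Gy).
#' @export
mean_dose <- function(ddvh) {
  stopifnot(inherits(ddvh, "ddvh"))
  if (ddvh$total_volume <= 0) stop("zero total volume")
  sum(ddvh$dose * ddvh$volume) / ddvh$total_volume
}

#' Restrict a differential DVH to its hottest subvolume
#'
#' Returns the DVH of the highest-dose `cap` cc, splitting the boundary bin
#' fractionally, as used for the 100 cc high-dose chest-wall region. If the
#' structure is no larger than `cap` the input is returned unchanged.
#'
#' @param ddvh A [ddvh()].
#' @param cap Subvolume cap in cc (> 0).
#' @return A [ddvh()] with total volume `min(cap, total_volume)`.
#' @export
hottest_subvolume <- function(ddvh, cap) {
  stopifnot(inherits(ddvh, "ddvh"))
  if (!is.numeric(cap) || cap <= 0) stop("cap must be > 0")
  if (ddvh$total_volume <= cap) return(ddvh)
  ord <- order(ddvh$dose, decreasing = TRUE)
  dose <- ddvh$dose[ord]
  vol <- ddvh$volume[ord]
  csum <- cumsum(vol)
  k <- which(csum >= cap - 1e-12 * cap)[1L]
  vol <- vol[seq_len(k)]
  vol[k] <- vol[k] - (csum[k] - cap)   # fractional boundary split
  keep <- vol > 0
  ddvh(
    dose = dose[seq_len(k)][keep], volume = vol[keep],
    total_volume = cap,
    structure = ddvh$structure, scale = ddvh$scale
  )
}

# drop zero-volume bins (internal; keeps generated DVHs compact)
.drop_empty_bins <- function(d) {
  keep <- d$volume > 0
  if (!any(keep)) keep[length(keep)] <- TRUE
  ddvh(d$dose[keep], d$volume[keep], total_volume = d$total_volume,
       structure = d$structure, scale = d$scale)
}

#' Relative volume fractions of a differential DVH
#'
#' @param ddvh A [ddvh()].
#' @return `volume / total_volume`.
#' @export
volume_fractions <- function(ddvh) {
  stopifnot(inherits(ddvh, "ddvh"))
  if (ddvh$total_volume <= 0) stop("zero total volume")
  ddvh$volume / ddvh$total_volume
}

#' Plot a cumulative DVH
#'
#' @param x A [cdvh()].
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::lines()] / [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cdvh <- function(x, add = FALSE, ...) {
  xlab <- switch(x$scale,
    EQD2 = "EQD2 (Gy)", BED = "BED (Gy)",
    relative = "Relative dose", "Dose (Gy)"
  )
  if (add) {
    graphics::lines(x$dose, x$volume, ...)
  } else {
    graphics::plot(x$dose, x$volume, type = "l", xlab = xlab,
                   ylab = "Volume (cc)", main = x$structure, ...)
  }
  invisible(x)
}
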