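#' Per-interval organic-carbon burial rates
#'
#' Burial in each dated interval is the product of the linear sediment
#' accumulation rate, dry bulk density and organic-carbon fraction:
#' `SAR [cm yr^-1] x dry bulk density [g cm^-3] x (%OC / 100)`, converted
#' from g C cm^-2 yr^-1 to the conventional g C m^-2 yr^-1 by the factor
#' 1e4.
#'
#' @param dated a `dated_profile` from [crs_date()] or [cic_date()].
#' @param oc_percent per-interval organic-carbon content (% dry mass). May be
#'   omitted when the dated profile already carries `oc_burial`.
#' @param dry_bulk_density per-interval density (g cm^-3); defaults to
#'   `dated$mar / dated$sar_linear`.
#' @return numeric vector of burial rates, g C m^-2 yr^-1.
#' @export
oc_burial_profile <- function(dated, oc_percent = NULL, dry_bulk_density = NULL) {
  stopifnot(inherits(dated, "dated_profile"))
  if (is.null(oc_percent)) {
    if (is.null(dated$oc_burial)) stop("oc_percent is required")
    return(dated$oc_burial)
  }
  if (any(oc_percent < 0 | oc_percent > 100))
    stop("oc_percent must lie in [0, 100]")
  if (is.null(dry_bulk_density)) dry_bulk_density <- dated$mar / dated$sar_linear
  dated$sar_linear * dry_bulk_density * oc_percent / 100 * 1e4
}

#' Mean recent burial rate over a time window
#'
#' Duration-weighted mean of the per-interval burial rates over the intervals
#' whose midpoint age falls within the window (default 100 yr, the upper end
#' of the ~50-100 yr horizon excess 210Pb can resolve). Weights are interval
#' durations (bottom-boundary age minus top-boundary age).
#'
#' @param burial per-interval burial rates (g C m^-2 yr^-1), or a
#'   `dated_profile` carrying `oc_burial`.
#' @param ages interval midpoint ages (yr); taken from the profile when
#'   `burial` is a `dated_profile`.
#' @param durations interval durations (yr); likewise.
#' @param window averaging window in years, within [50, 150].
#' @return scalar mean burial rate, g C m^-2 yr^-1.
#' @export
recent_mean_burial <- function(burial, ages = NULL, durations = NULL,
                               window = 100) {
  if (inherits(burial, "dated_profile")) {
    dated <- burial
    burial <- dated$oc_burial
    if (is.null(ages)) ages <- dated$age
    if (is.null(durations)) durations <- dated$age_bot - dated$age_top
  }
  if (window < 50 || window > 150)
    stop("window must lie in [50, 150] yr")
  if (is.null(durations)) durations <- rep(1, length(burial))
  keep <- is.finite(ages) & ages <= window & is.finite(burial)
  if (!any(keep)) stop("no dated interval younger than the window")
  w <- durations[keep]
  if (any(!is.finite(w) | w <= 0)) w[!is.finite(w) | w <= 0] <- min(w[is.finite(w) & w > 0], 1)
  sum(burial[keep] * w) / sum(w)
}

#' Default sediment-focusing-factor table
#'
#' Sediment focusing concentrates accumulation in the depocenter, so a rate
#' from a single deep-spot core overestimates the whole-lake mean; dividing
#' by a sediment focusing factor (SFF) corrects this. Neither the depth-class
#' SFF values nor the slope relation are fixed by theory; the defaults below
#' are assumptions in the spirit of the morphometric literature and should be
#' overridden with system-specific values (see [read_sff_table()]) whenever
#' these are available. Depth classes are `<=5`, `>5-10`, `>10-30`, `>30-90`
#' and `>90` m of maximum depth; the slope relation is
#' `SFF = max(1, a + b * slope%)`.
#'
#' @return list with `depth_breaks`, `depth_labels`, `sff_values` (one per
#'   depth class) and `slope_coeffs` (`a`, `b`).
#' @export
default_sff_table <- function() {
  list(depth_breaks = c(0, 5, 10, 30, 90, Inf),
       depth_labels = c("<=5 m", ">5-10 m", ">10-30 m", ">30-90 m", ">90 m"),
       sff_values = c(1.0, 1.5, 2.0, 2.5, 3.0),
       slope_coeffs = c(a = 1, b = 0.056))
}

#' Read a sediment-focusing-factor table from YAML
#'
#' Expected keys: `depth_classes` (list of `max_depth` upper bounds, the last
#' one `.inf` or omitted, with `sff`) and `slope_coeffs` (`a`, `b`).
#'
#' @param path YAML file path.
#' @return list in the format of [default_sff_table()].
#' @export
read_sff_table <- function(path) {
  y <- yaml::read_yaml(path)
  ub <- vapply(y$depth_classes, function(d)
    if (is.null(d$max_depth) || identical(d$max_depth, ".inf")) Inf
    else as.numeric(d$max_depth), numeric(1))
  vals <- vapply(y$depth_classes, function(d) as.numeric(d$sff), numeric(1))
  if (is.unsorted(ub)) stop("depth classes must be in increasing depth order")
  if (any(vals <= 0)) stop("SFF values must be > 0")
  lab <- paste0(c("<=", rep(">", length(ub) - 1)),
                c(ub[1], paste0(utils::head(ub, -1), "-", utils::tail(ub, -1))[-1]))
  tab <- default_sff_table()
  tab$depth_breaks <- c(0, ub)
  tab$depth_labels <- c(lab[1], paste0(">", utils::head(ub, -1), "-", utils::tail(ub, -1))[-1])
  tab$sff_values <- vals
  if (!is.null(y$slope_coeffs))
    tab$slope_coeffs <- c(a = as.numeric(y$slope_coeffs$a),
                          b = as.numeric(y$slope_coeffs$b))
  tab
}

sff_from_depth <- function(max_depth, sff_table) {
  if (is.na(max_depth) || max_depth < 0) stop("max_depth must be >= 0")
  idx <- findInterval(max_depth, sff_table$depth_breaks,
                      left.open = TRUE, rightmost.closed = FALSE)
  idx <- max(idx, 1L)  # depth 0 falls in the shallowest class
  sff_table$sff_values[idx]
}

sff_from_slope <- function(mean_slope, sff_table) {
  if (is.na(mean_slope) || mean_slope < 0) stop("mean_slope must be >= 0")
  co <- sff_table$slope_coeffs
  max(1, unname(co["a"] + co["b"] * mean_slope))
}

#' Whole-lake burial rate from core rates
#'
#' Three alternative estimators, chosen by the data available for a lake:
#' method 1 averages rates from two or more cores spread over the basin;
#' method 2 divides a single depocenter-core rate by a sediment focusing
#' factor derived from the mean basin slope; method 3 divides it by the SFF
#' of the lake's maximum-depth class.
#'
#' @param core_rates numeric vector of core-level recent burial rates
#'   (g C m^-2 yr^-1); length >= 2 for method 1, exactly 1 otherwise.
#' @param method 1, 2 or 3.
#' @param mean_slope mean basin slope (%), method 2 only.
#' @param max_depth lake maximum depth (m), method 3 only.
#' @param sff_table an SFF table, see [default_sff_table()].
#' @param lake_id identifier carried into the result.
#' @return list of class `whole_lake_rate`: `lake_id`, `rate`
#'   (g C m^-2 yr^-1), `method`, `n_cores`, `sff_used` (NA for method 1).
#' @export
whole_lake_rate <- function(core_rates, method,
                            mean_slope = NULL, max_depth = NULL,
                            sff_table = default_sff_table(),
                            lake_id = "lake") {
  if (any(core_rates < 0)) stop("core rates must be >= 0")
  method <- as.integer(method)
  if (method == 1L) {
    if (length(core_rates) < 2L) stop("method 1 requires >= 2 core rates")
    rate <- mean(core_rates); sff <- NA_real_
  } else if (method %in% c(2L, 3L)) {
    if (length(core_rates) != 1L)
      stop("methods 2 and 3 use exactly one depocenter core rate")
    sff <- if (method == 2L) {
      if (is.null(mean_slope)) stop("method 2 requires mean_slope")
      sff_from_slope(mean_slope, sff_table)
    } else {
      if (is.null(max_depth)) stop("method 3 requires max_depth")
      sff_from_depth(max_depth, sff_table)
    }
    rate <- core_rates / sff
  } else stop("method must be 1, 2 or 3")
  structure(list(lake_id = lake_id, rate = unname(rate), method = method,
                 n_cores = length(core_rates), sff_used = unname(sff)),
            class = "whole_lake_rate")
}

#' @export
print.whole_lake_rate <- function(x, ...) {
  cat(sprintf("<whole_lake_rate> lake '%s': %.2f g C m-2 yr-1 (method %d, %d core%s%s)\n",
              x$lake_id, x$rate, x$method, x$n_cores,
              if (x$n_cores > 1) "s" else "",
              if (is.na(x$sff_used)) "" else sprintf(", SFF %.2f", x$sff_used)))
  invisible(x)
}
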