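#' @title Lead-210 decay constant
#' @description Decay constant of 210Pb, `log(2) / 22.3` yr^-1 (half-life
#'   22.3 yr). Exported so that analyses and generators share one value.
#' @export
PB210_LAMBDA <- log(2) / 22.3

#' Assemble and validate a sediment-core profile
#'
#' A `core_profile` holds the per-interval radiometric and geochemical
#' measurements of one sediment core, ordered from the sediment surface
#' downward. Intervals must be contiguous slabs (each interval starts where
#' the previous one ends).
#'
#' @param intervals data.frame with one row per interval and columns
#'   `top_depth` (cm below the sediment surface), `thickness` (cm),
#'   `dry_bulk_density` (g cm^-3), `pb210_total` (Bq kg^-1), `ra226`
#'   (Bq kg^-1), `oc_percent` (% dry mass); optional columns
#'   `pb210_total_err` (Bq kg^-1), `d13c` (permil vs VPDB), `cn_molar`.
#' @param lake_id character identifier of the lake/core.
#' @param collection_year calendar year the core was collected.
#' @return An object of class `core_profile`: the interval data.frame with
#'   attributes `lake_id` and `collection_year`.
#' @examples
#' prof <- core_profile(data.frame(
#'   top_depth = c(0, 2, 4), thickness = 2, dry_bulk_density = 0.5,
#'   pb210_total = c(250, 120, 60), ra226 = 25, oc_percent = 4),
#'   lake_id = "L1", collection_year = 2015)
#' @export
core_profile <- function(intervals, lake_id = "core", collection_year = NULL) {
  required <- c("top_depth", "thickness", "dry_bulk_density",
                "pb210_total", "ra226", "oc_percent")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols))
    stop("core profile is missing column(s): ", paste(missing_cols, collapse = ", "))
  intervals <- as.data.frame(intervals)
  n <- nrow(intervals)
  if (n < 1L) stop("core profile must contain at least one interval")
  with(intervals, {
    if (any(top_depth < 0)) stop("top_depth must be >= 0")
    if (any(thickness <= 0)) stop("thickness must be > 0")
    if (any(dry_bulk_density <= 0)) stop("dry_bulk_density must be > 0")
    if (any(oc_percent < 0 | oc_percent > 100)) stop("oc_percent must lie in [0, 100]")
    bad <- !is.na(pb210_total) & pb210_total < 0 | !is.na(ra226) & ra226 < 0
    if (any(bad)) stop("activities must be >= 0")
  })
  if (n > 1L) {
    expected_top <- intervals$top_depth[-n] + intervals$thickness[-n]
    if (any(abs(intervals$top_depth[-1L] - expected_top) > 1e-6))
      stop("intervals must be contiguous and strictly increasing in depth")
  }
  structure(intervals, class = c("core_profile", "data.frame"),
            lake_id = lake_id, collection_year = collection_year)
}

#' @export
print.core_profile <- function(x, ...) {
  cat(sprintf("<core_profile> lake '%s', %d intervals, 0-%g cm%s\n",
              attr(x, "lake_id"), nrow(x),
              x$top_depth[nrow(x)] + x$thickness[nrow(x)],
              if (is.null(attr(x, "collection_year"))) ""
              else sprintf(", collected %d", attr(x, "collection_year"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more intervals)\n", sep = "")
  invisible(x)
}

#' Unsupported (excess) 210Pb activity
#'
#' Excess 210Pb is the total 210Pb activity minus the 226Ra-supported
#' component. Values at or below zero indicate radiometric equilibrium; to
#' keep the logarithms of the age models finite they are clamped to a small
#' positive floor and flagged.
#'
#' @param profile a [core_profile()].
#' @param floor_frac floor for clamped values, as a fraction of the surface
#'   excess (default 0.001, i.e. 0.1 %).
#' @return data.frame with columns `excess` (Bq kg^-1) and `clamped`
#'   (logical; TRUE where the raw difference was below the floor).
#' @export
excess_pb210 <- function(profile, floor_frac = 0.001) {
  stopifnot(inherits(profile, "core_profile"))
  bad <- which(is.na(profile$pb210_total) | is.na(profile$ra226))
  if (length(bad))
    stop("missing 210Pb or 226Ra activity at interval(s): ",
         paste(bad, collapse = ", "))
  excess <- profile$pb210_total - profile$ra226
  if (is.na(excess[1L]) || excess[1L] <= 0)
    stop("surface excess 210Pb must be positive for dating")
  floor_val <- floor_frac * excess[1L]
  clamped <- excess < floor_val
  excess[clamped] <- floor_val
  data.frame(excess = excess, clamped = clamped)
}

#' Cumulative excess-210Pb inventory below each depth
#'
#' Each interval contributes `excess x dry_bulk_density x thickness` (with
#' Bq kg^-1 converted to Bq g^-1), integrated by the rectangular rule that
#' matches slab sampling. The inventory below a depth is the sum of
#' contributions from that depth to the bottom of the core plus, optionally,
#' a tail term for unmeasured sediment below the deepest interval obtained by
#' log-linear extrapolation of excess against cumulative mass fitted to the
#' deepest three intervals.
#'
#' @param profile a [core_profile()].
#' @param excess optional result of [excess_pb210()]; computed if missing.
#' @param tail logical; extrapolate the inventory in unmeasured sediment
#'   below the deepest non-equilibrium interval (default TRUE). With
#'   `tail = FALSE` the profile must reach equilibrium (bottom excess below
#'   `complete_frac` of the surface excess).
#' @param complete_frac bottom excess below this fraction of the surface
#'   excess is treated as equilibrium (default 0.01).
#' @param n_tail_fit number of deepest non-clamped intervals used in the
#'   log-linear tail fit (default 3).
#' @details Intervals below the deepest non-clamped (non-equilibrium)
#'   interval carry no unsupported inventory and are excluded from dating
#'   (`datable = FALSE`). The tail is the geometric sum of extrapolated slab
#'   contributions of a continued exponential decay, which reproduces an
#'   exactly exponential profile with zero error. Midpoint inventories use
#'   geometric interpolation between the slab boundaries, consistent with
#'   exponential decay within a slab.
#' @return list with per-interval vectors `contribution`, `inventory_top`,
#'   `inventory_mid` (Bq cm^-2), `cum_mass_top`, `cum_mass_mid` (g cm^-2),
#'   `datable` (logical), and scalars `tail_inventory` and `total_inventory`
#'   (Bq cm^-2).
#' @export
cumulative_inventory <- function(profile, excess = NULL, tail = TRUE,
                                 complete_frac = 0.01, n_tail_fit = 3L) {
  stopifnot(inherits(profile, "core_profile"))
  if (is.null(excess)) excess <- excess_pb210(profile)
  exc <- excess$excess
  n <- nrow(profile)
  ok <- which(!excess$clamped)
  if (!length(ok)) stop("no interval above 210Pb equilibrium")
  last_ok <- max(ok)
  # Bq kg^-1 -> Bq g^-1, times areal mass of the slab (g cm^-2) -> Bq cm^-2
  dm <- profile$dry_bulk_density * profile$thickness
  contribution <- (exc / 1000) * dm
  contribution[seq_len(n) > last_ok] <- 0  # equilibrium zone
  cum_mass_bot <- cumsum(dm)
  cum_mass_top <- cum_mass_bot - dm
  cum_mass_mid <- cum_mass_top + dm / 2

  bottom_frac <- exc[last_ok] / exc[1L]
  tail_inventory <- 0
  if (!tail) {
    if (bottom_frac > complete_frac)
      stop("incomplete inventory: excess 210Pb has not reached equilibrium ",
           "at the core bottom and tail extrapolation is disabled")
  } else {
    idx <- utils::tail(ok, n_tail_fit)
    if (length(idx) >= 3L) {
      fit <- stats::lm(log(exc[idx]) ~ cum_mass_mid[idx])
      alpha <- unname(stats::coef(fit)[1L])
      beta <- unname(stats::coef(fit)[2L])
      if (is.finite(beta) && beta < 0) {
        # geometric sum of continued slab contributions below the last
        # non-equilibrium slab
        dmt <- mean(dm[idx])
        m0 <- cum_mass_bot[last_ok]
        tail_inventory <- exp(alpha + beta * (m0 + dmt / 2)) * dmt / 1000 /
          (1 - exp(beta * dmt))
      } else if (bottom_frac > complete_frac) {
        warning("excess 210Pb does not decay toward the core bottom; ",
                "tail inventory set to zero")
      }
    } else if (bottom_frac > complete_frac) {
      stop("tail extrapolation needs at least 3 non-equilibrium intervals")
    }
  }
  inventory_top <- rev(cumsum(rev(contribution))) + tail_inventory
  inventory_bot <- inventory_top - contribution
  inventory_mid <- ifelse(inventory_bot > 0,
                          sqrt(inventory_top * inventory_bot),
                          inventory_top - contribution / 2)
  datable <- seq_len(n) <= last_ok & inventory_mid > 0
  list(contribution = contribution,
       inventory_top = inventory_top,
       inventory_mid = inventory_mid,
       cum_mass_top = cum_mass_top,
       cum_mass_mid = cum_mass_mid,
       datable = datable,
       tail_inventory = tail_inventory,
       total_inventory = inventory_top[1L])
}

new_dated_profile <- function(df, profile, model, total_inventory = NA_real_) {
  structure(df, class = c("dated_profile", "data.frame"),
            lake_id = attr(profile, "lake_id"),
            collection_year = attr(profile, "collection_year"),
            model = model, total_inventory = total_inventory)
}

#' @export
print.dated_profile <- function(x, ...) {
  cat(sprintf("<dated_profile> lake '%s', model %s, %d intervals, ages %.1f-%.1f yr\n",
              attr(x, "lake_id"), attr(x, "model"), nrow(x),
              min(x$age), max(x$age)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more intervals)\n", sep = "")
  invisible(x)
}

#' Date a core with the constant-rate-of-supply (CRS) model
#'
#' The CRS model assumes a constant flux of unsupported 210Pb to the sediment
#' surface. The age of a depth z is `(1/lambda) * log(I0 / I(z))` where `I0`
#' is the whole-core excess inventory and `I(z)` the inventory below z; the
#' mass accumulation rate at z is `lambda * I(z) / C(z)` with `C(z)` the
#' excess concentration. Quantities are reported at interval mass midpoints.
#'
#' @param profile a [core_profile()] with at least 3 intervals.
#' @param tail,floor_frac,complete_frac passed to [cumulative_inventory()]
#'   and [excess_pb210()].
#' @param max_age dating-window limit (yr); older intervals are flagged
#'   `beyond_range` but still reported (default 150).
#' @return A `dated_profile`: data.frame with per-interval `mid_depth` (cm),
#'   `pb210_excess` (Bq kg^-1), `cum_mass_above` (g cm^-2), `inventory_below`
#'   (Bq cm^-2), `age`, `age_top`, `age_bot` (yr before collection),
#'   `sar_linear` (cm yr^-1), `mar` (g cm^-2 yr^-1), `oc_burial`
#'   (g C m^-2 yr^-1), and flags `beyond_range`, `clamped`.
#' @seealso [cic_date()], [oc_burial_profile()]
#' @export
crs_date <- function(profile, tail = TRUE, floor_frac = 0.001,
                     complete_frac = 0.01, max_age = 150) {
  stopifnot(inherits(profile, "core_profile"))
  if (nrow(profile) < 3L) stop("dating requires at least 3 intervals")
  exc <- excess_pb210(profile, floor_frac = floor_frac)
  inv <- cumulative_inventory(profile, exc, tail = tail,
                              complete_frac = complete_frac)
  lambda <- PB210_LAMBDA
  total <- inv$total_inventory
  if (total <= 0 || any(inv$inventory_mid[inv$datable] >= total + 1e-12))
    stop("total inventory must exceed the inventory below every dated depth")
  dat <- inv$datable
  if (!all(dat))
    warning("profile truncated at the 210Pb equilibrium depth: ",
            sum(!dat), " interval(s) not datable")
  age <- age_top <- age_bot <- mar <- rep(NA_real_, nrow(profile))
  inv_bot <- inv$inventory_top - inv$contribution
  age[dat] <- log(total / inv$inventory_mid[dat]) / lambda
  age_top[dat] <- log(total / inv$inventory_top[dat]) / lambda
  age_bot[dat] <- ifelse(inv_bot[dat] > 0,
                         log(total / inv_bot[dat]) / lambda, Inf)
  mar[dat] <- lambda * inv$inventory_mid[dat] / (exc$excess[dat] / 1000)
  sar <- mar / profile$dry_bulk_density
  burial <- mar * profile$oc_percent / 100 * 1e4
  df <- data.frame(
    mid_depth = profile$top_depth + profile$thickness / 2,
    pb210_excess = exc$excess,
    cum_mass_above = inv$cum_mass_mid,
    inventory_below = inv$inventory_mid,
    age = age, age_top = age_top, age_bot = age_bot,
    sar_linear = sar, mar = mar, oc_burial = burial,
    beyond_range = !is.na(age) & age > max_age,
    clamped = exc$clamped)
  if (!is.null(profile$d13c)) df$d13c <- profile$d13c
  if (!is.null(profile$cn_molar)) df$cn_molar <- profile$cn_molar
  if (any(df$beyond_range))
    message(sum(df$beyond_range), " interval(s) older than ", max_age,
            " yr flagged as beyond the 210Pb dating range")
  new_dated_profile(df, profile, "CRS", total)
}

#' Date a core with the constant-initial-concentration (CIC) model
#'
#' The CIC model assumes the excess 210Pb concentration deposited at the
#' surface has been constant through time, so the age of depth z is
#' `(1/lambda) * log(C(0) / C(z))`. Because each measurement is a slab
#' average, the ratio of a slab's activity to the surface slab's activity
#' estimates the age of the slab's top boundary; midpoint ages are the mean
#' of the two boundary ages and linear sediment accumulation rates are
#' per-slab depth/age quotients. Inversions of the excess profile
#' (concentration increasing with depth) violate the model; they are
#' monotonized by a running minimum from the surface, with a warning when
#' the adjustment is material.
#'
#' @inheritParams crs_date
#' @param inversion_tol warn when monotonization changes any excess value by
#'   more than this relative amount (default 0.05).
#' @return A `dated_profile` (see [crs_date()]); `inventory_below` and
#'   `cum_mass_above` are carried over from the inventory computation.
#' @export
cic_date <- function(profile, tail = TRUE, floor_frac = 0.001,
                     complete_frac = 0.01, max_age = 150,
                     inversion_tol = 0.05) {
  stopifnot(inherits(profile, "core_profile"))
  if (nrow(profile) < 3L) stop("dating requires at least 3 intervals")
  exc <- excess_pb210(profile, floor_frac = floor_frac)
  raw <- exc$excess
  mono <- cummin(raw)
  if (any(mono < raw * (1 - 1e-12))) {
    rel <- max((raw - mono) / raw)
    if (rel > inversion_tol)
      warning(sprintf(paste0("excess 210Pb increases with depth (max relative",
                             " inversion %.1f%%); profile monotonized"),
                      100 * rel))
  }
  lambda <- PB210_LAMBDA
  inv <- cumulative_inventory(profile, exc, tail = tail,
                              complete_frac = complete_frac)
  mid <- profile$top_depth + profile$thickness / 2
  n <- length(mid)
  # slab-average ratios estimate top-boundary ages (surface slab top = 0)
  age_top <- log(mono[1L] / mono) / lambda
  age_bot <- c(age_top[-1L],
               if (n >= 2L) age_top[n] + (age_top[n] - age_top[n - 1L])
               else age_top[n])
  age <- (age_top + age_bot) / 2
  dt <- age_bot - age_top
  sar <- ifelse(dt > 0, profile$thickness / dt, NA_real_)
  mar <- sar * profile$dry_bulk_density
  burial <- mar * profile$oc_percent / 100 * 1e4
  df <- data.frame(
    mid_depth = mid,
    pb210_excess = mono,
    cum_mass_above = inv$cum_mass_mid,
    inventory_below = inv$inventory_mid,
    age = age, age_top = age_top, age_bot = age_bot,
    sar_linear = sar, mar = mar, oc_burial = burial,
    beyond_range = age > max_age,
    clamped = exc$clamped)
  if (!is.null(profile$d13c)) df$d13c <- profile$d13c
  if (!is.null(profile$cn_molar)) df$cn_molar <- profile$cn_molar
  new_dated_profile(df, profile, "CIC", inv$total_inventory)
}
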