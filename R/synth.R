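#' Scenario for a synthetic 210Pb core
#'
#' Describes the generative model of a constant-flux core: a prescribed flux
#' of unsupported 210Pb to the sediment surface, a mass-accumulation history,
#' an organic-carbon history, a supported (226Ra) background and a
#' multiplicative measurement noise level. The defaults give a 60 cm core in
#' 2 cm slabs with supported activity 25 Bq kg^-1 and a flux chosen so the
#' surface excess is about ten times the supported level.
#'
#' @param mar mass accumulation rate: scalar (g cm^-2 yr^-1) or a function
#'   of age (yr).
#' @param flux unsupported-210Pb flux to the surface, Bq cm^-2 yr^-1.
#' @param oc organic-carbon content: scalar (% dry mass) or a function of
#'   age.
#' @param supported supported 210Pb (= 226Ra) activity, Bq kg^-1.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (lognormal, mean-one) noise applied to the excess activity; 0 for a
#'   noiseless core.
#' @param interval_cm slab thickness, cm.
#' @param core_cm core length, cm.
#' @param density dry bulk density, g cm^-3 (constant).
#' @param seed integer seed.
#' @return list of class `core_scenario`.
#' @export
core_scenario <- function(mar = 0.1, flux = NULL, oc = 4, supported = 25,
                          noise_cv = 0, interval_cm = 2, core_cm = 60,
                          density = 0.5, seed = 1) {
  mar_fun <- if (is.function(mar)) mar else function(age) rep_len(mar, length(age))
  if (any(mar_fun(seq(0, 500, by = 10)) <= 0)) stop("mar history must be > 0")
  if (is.null(flux)) {
    # surface excess ten times the supported level, or 250 Bq kg^-1 when
    # there is no supported background to scale from
    surf_conc <- if (supported > 0) 10 * supported / 1000 else 0.25
    flux <- surf_conc * mar_fun(0)
  }
  if (flux <= 0) stop("flux must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  oc_fun <- if (is.function(oc)) oc else function(age) rep_len(oc, length(age))
  structure(list(mar = mar_fun, flux = flux, oc = oc_fun,
                 supported = supported, noise_cv = noise_cv,
                 interval_cm = interval_cm, core_cm = core_cm,
                 density = density, seed = seed),
            class = "core_scenario")
}

# age at given cumulative masses (g cm^-2) under a mar(t) history
age_at_mass <- function(mass, mar_fun, dt = 0.05) {
  t_grid <- seq(0, 2000, by = dt)
  m_grid <- cumsum(c(0, mar_fun(t_grid[-1] - dt / 2) * dt))
  if (max(mass) > max(m_grid)) stop("mar history too short for the core mass")
  stats::approx(m_grid, t_grid, xout = mass)$y
}

#' Generate a synthetic 210Pb core with its truth record
#'
#' Implements the constant-rate-of-supply premise exactly: the excess
#' concentration deposited at age t is `flux / mar(t)` and decays with the
#' 210Pb constant, so the slab-average excess activity is computed in closed
#' form from the ages of the slab boundaries. Multiplicative lognormal noise
#' (mean one, CV `noise_cv`) is then applied to the excess component of the
#' total activity.
#'
#' @param scenario a [core_scenario()].
#' @param lake_id,collection_year metadata for the generated profile.
#' @return list with `profile` (a [core_profile()]) and `truth` (data.frame
#'   with per-interval `mid_depth`, `age`, `mar`, `sar`, `oc_percent`,
#'   `oc_burial`, the generative values before noise).
#' @export
make_core <- function(scenario = core_scenario(), lake_id = "synthetic",
                      collection_year = 2015) {
  stopifnot(inherits(scenario, "core_scenario"))
  set.seed(scenario$seed)
  lambda <- PB210_LAMBDA
  depth_top <- seq(0, scenario$core_cm - scenario$interval_cm,
                   by = scenario$interval_cm)
  n <- length(depth_top)
  dm <- rep(scenario$density * scenario$interval_cm, n)
  m_bnd <- c(0, cumsum(dm))
  t_bnd <- age_at_mass(m_bnd, scenario$mar)
  # slab-average excess concentration (Bq g^-1), exact under the CRS premise:
  # integral of C dm over a slab equals (flux/lambda)(e^-lt_top - e^-lt_bot)
  cbar <- scenario$flux * (exp(-lambda * t_bnd[-(n + 1)]) -
                           exp(-lambda * t_bnd[-1])) / (lambda * dm)
  excess_true <- cbar * 1000  # Bq kg^-1
  if (scenario$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$noise_cv^2))
    excess_obs <- excess_true * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  } else excess_obs <- excess_true
  m_mid <- (m_bnd[-(n + 1)] + m_bnd[-1]) / 2
  t_mid <- age_at_mass(m_mid, scenario$mar)
  mar_mid <- scenario$mar(t_mid)
  oc_mid <- scenario$oc(t_mid)
  profile <- core_profile(data.frame(
    top_depth = depth_top,
    thickness = scenario$interval_cm,
    dry_bulk_density = scenario$density,
    pb210_total = excess_obs + scenario$supported,
    ra226 = scenario$supported,
    oc_percent = oc_mid),
    lake_id = lake_id, collection_year = collection_year)
  truth <- data.frame(
    mid_depth = depth_top + scenario$interval_cm / 2,
    age = t_mid, mar = mar_mid, sar = mar_mid / scenario$density,
    oc_percent = oc_mid,
    oc_burial = mar_mid * oc_mid / 100 * 1e4)
  list(profile = profile, truth = truth)
}

#' Default per-class scenario for a synthetic global lake dataset
#'
#' One row per lake class observed in a global synthesis: the class label,
#' number of lakes, the targeted arithmetic mean and standard error of the
#' burial-rate population (g C m^-2 yr^-1), a class-typical annual air
#' temperature (mean and SD, degrees C), and covariates (biome, land cover)
#' consistent with the class. The burial targets are the class-level moments
#' such a synthesis reports; the human-altered classes share one mean
#' (burial in anthropic lakes being largely insensitive to temperature).
#'
#' @return data.frame, one row per class.
#' @export
default_class_scenario <- function() {
  data.frame(
    label = c("Humid tropical forest", "Temperate forest", "Boreal forest",
              "Other mid-latitude", "Subpolar and polar",
              "Cold anthropic", "Moderate anthropic", "Warm anthropic"),
    n = c(44L, 161L, 25L, 16L, 9L, 90L, 29L, 24L),
    mean = c(113.5, 38.9, 36.7, 15.4, 10.9, 47.6, 47.6, 47.6),
    se = c(18.1, 8.4, 3.2, 3.9, 2.7, 3.1, 3.1, 3.1),
    temp_mean = c(26, 9, 0, 8, -8, 4, 11, 20),
    temp_sd = c(2, 3, 3, 4, 4, 1.5, 1.5, 2),
    biome = c("Humid tropical forest", "Temperate forest", "Boreal forest",
              "Other mid-latitude", "Subpolar and polar",
              "Temperate forest", "Temperate forest", "Humid tropical forest"),
    land_cover = c("forest", "forest", "forest", "grassland", "tundra",
                   "cropland", "cropland", "cropland"),
    stringsAsFactors = FALSE)
}

rlnorm_matched <- function(n, mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - sigma2 / 2, sqrt(sigma2))
}

# draw from N(mu, sd) truncated to (lo, hi) by inverse CDF
rnorm_trunc <- function(n, mu, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(p, mu, sd)
}

#' Generate a synthetic classified lake dataset
#'
#' Burial rates per class are drawn from lognormal distributions whose first
#' two moments match each class's target mean and population SD
#' (`se * sqrt(n)`); temperatures are normal per class, truncated to the
#' class's anthropic temperature bin where one applies so that
#' classification is consistent with the intended class.
#'
#' @param scenario data.frame in the format of [default_class_scenario()];
#'   `n` may be overridden per class via `n_per_class`.
#' @param n_per_class optional single count replacing every class's `n`.
#' @param seed integer seed.
#' @return data.frame of lake records: `lake_id`, `latitude`, `longitude`,
#'   `biome`, `land_cover`, `annual_temp`, `burial`, `class` (the generating
#'   class, identical to `classify_lake()` output on the covariates).
#' @export
make_lake_dataset <- function(scenario = default_class_scenario(),
                              n_per_class = NULL, seed = 1) {
  if (any(scenario$mean <= 0)) stop("target class means must be > 0")
  # population SD implied by the class SE at its study sample size; fixed
  # before any resizing so n_per_class changes cohort size, not the
  # population being sampled
  if (is.null(scenario$sd_pop))
    scenario$sd_pop <- scenario$se * sqrt(scenario$n)
  if (!is.null(n_per_class)) scenario$n <- as.integer(n_per_class)
  if (any(scenario$n < 1L)) stop("class n must be >= 1")
  set.seed(seed)
  bins <- list("Cold anthropic" = c(-30, 7.5 - 1e-6),
               "Moderate anthropic" = c(7.5, 15.0),
               "Warm anthropic" = c(15.0 + 1e-6, 40))
  out <- do.call(rbind, lapply(seq_len(nrow(scenario)), function(i) {
    s <- scenario[i, ]
    burial <- rlnorm_matched(s$n, s$mean, s$sd_pop)
    bin <- bins[[s$label]]
    if (is.null(bin)) bin <- c(-30, 40)
    temp <- rnorm_trunc(s$n, s$temp_mean, s$temp_sd, bin[1], bin[2])
    data.frame(lake_id = sprintf("%s_%03d", gsub("[^A-Za-z]", "", s$label), seq_len(s$n)),
               latitude = stats::runif(s$n, -60, 70),
               longitude = stats::runif(s$n, -180, 180),
               biome = s$biome, land_cover = s$land_cover,
               annual_temp = temp, burial = burial,
               class = s$label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate (delta-13C, C:N) samples with known source labels
#'
#' Samples are allocated to sources by largest-remainder rounding of the
#' requested proportions, drawn uniformly inside each source's rectangle,
#' and optionally jittered; the unallocated remainder is drawn from a margin
#' region outside every rectangle so it is unclassifiable by construction.
#'
#' @param endmembers an [endmember_set()].
#' @param proportions named numeric vector (names matching the endmember
#'   sources), summing to at most 1.
#' @param n number of samples.
#' @param jitter SD of Gaussian jitter added to both coordinates (permil /
#'   ratio units).
#' @param seed integer seed.
#' @return list with `signatures` (data.frame `lake_id`, `d13c`, `cn_molar`)
#'   and `truth` (character vector of generating sources, `NA` for the
#'   margin draws).
#' @export
make_source_samples <- function(endmembers = default_endmembers(),
                                proportions, n, jitter = 0, seed = 1) {
  stopifnot(inherits(endmembers, "endmember_set"))
  bad <- setdiff(names(proportions), endmembers$source)
  if (length(bad)) stop("unknown source(s): ", paste(bad, collapse = ", "))
  if (any(proportions < 0) || sum(proportions) > 1 + 1e-9)
    stop("proportions must be >= 0 and sum to at most 1")
  if (jitter > 0 && any_overlap(endmembers))
    warning("endmember rectangles overlap; jitter may create ambiguous points")
  set.seed(seed)
  target <- proportions * n
  counts <- floor(target)
  rem <- max(0, round(sum(proportions) * n) - sum(counts))
  if (rem > 0) {
    frac_order <- order(target - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1L
  }
  n_out <- n - sum(counts)
  rows <- list(); truth <- character(0)
  for (lab in names(counts)) {
    k <- counts[[lab]]
    if (k == 0) next
    e <- endmembers[endmembers$source == lab, ]
    rows[[lab]] <- data.frame(d13c = stats::runif(k, e$d13c_min, e$d13c_max),
                              cn_molar = stats::runif(k, e$cn_min, e$cn_max))
    truth <- c(truth, rep(lab, k))
  }
  if (n_out > 0) {
    margin_lo <- max(endmembers$d13c_max) + 1
    rows[["_margin"]] <- data.frame(
      d13c = stats::runif(n_out, margin_lo, min(margin_lo + 2, -0.5)),
      cn_molar = stats::runif(n_out, min(endmembers$cn_min), max(endmembers$cn_max)))
    truth <- c(truth, rep(NA_character_, n_out))
  }
  sig <- do.call(rbind, rows)
  if (jitter > 0) {
    sig$d13c <- sig$d13c + stats::rnorm(nrow(sig), 0, jitter)
    sig$cn_molar <- sig$cn_molar + stats::rnorm(nrow(sig), 0, jitter)
  }
  sig <- data.frame(lake_id = sprintf("s%04d", seq_len(nrow(sig))), sig)
  rownames(sig) <- NULL
  list(signatures = sig, truth = truth)
}

any_overlap <- function(endmembers) {
  k <- nrow(endmembers)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- endmembers[i, ]; b <- endmembers[j, ]
    if (a$d13c_min < b$d13c_max && b$d13c_min < a$d13c_max &&
        a$cn_min < b$cn_max && b$cn_min < a$cn_max) return(TRUE)
  }
  FALSE
}

#' Generate an exponential forest-cover / burial gradient
#'
#' Burial follows `a * exp(b * forest%)` with multiplicative lognormal noise
#' of the given CV, emulating the relationship between lake burial and the
#' relative area of non-flooded forest around floodplain lakes.
#'
#' @param forest_pct covariate values (% non-flooded forest).
#' @param a,b model coefficients.
#' @param noise_cv multiplicative (lognormal, mean-one) noise CV; the
#'   realistic error structure for positive, right-skewed rates.
#' @param noise_sd SD of additive Gaussian noise, the homoscedastic error
#'   structure assumed by unweighted nonlinear least squares; useful for
#'   calibration checks of the fitting machinery. Only one of `noise_cv`
#'   and `noise_sd` may be positive.
#' @param seed integer seed.
#' @return data.frame with columns `forest_pct` and `burial`.
#' @export
make_forest_gradient <- function(forest_pct = seq(0, 100, by = 10),
                                 a = 56.21, b = 0.01608,
                                 noise_cv = 0, noise_sd = 0, seed = 1) {
  if (a <= 0) stop("a must be > 0")
  if (noise_cv > 0 && noise_sd > 0)
    stop("use either multiplicative (noise_cv) or additive (noise_sd) noise")
  set.seed(seed)
  y <- a * exp(b * forest_pct)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    y <- y * stats::rlnorm(length(y), -sdlog^2 / 2, sdlog)
  } else if (noise_sd > 0) {
    y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 1e-6)
  }
  data.frame(forest_pct = forest_pct, burial = y)
}
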