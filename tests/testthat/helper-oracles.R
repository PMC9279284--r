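# Closed-form oracles and small profile builders shared across tests.

# Slab-average activities (Bq kg^-1) of an exponential excess profile
# C(m) = c0 * exp(-k m) (c0 in Bq kg^-1, m cumulative mass g cm^-2):
# the slab average over [m_top, m_bot] is the exact integral / slab mass.
slab_average_exponential <- function(c0, k, mass_top, mass_bot) {
  c0 * (exp(-k * mass_top) - exp(-k * mass_bot)) / (k * (mass_bot - mass_top))
}

# Analytic inventory below mass m for the same profile, Bq cm^-2.
analytic_inventory_below <- function(c0, k, m) {
  (c0 / 1000) * exp(-k * m) / k
}

# Build a core_profile from an excess-activity vector (Bq kg^-1).
profile_from_excess <- function(excess, supported = 25, rho = 0.5,
                                thickness = 2, oc = 4, ...) {
  n <- length(excess)
  core_profile(data.frame(
    top_depth = (seq_len(n) - 1) * thickness,
    thickness = thickness,
    dry_bulk_density = rho,
    pb210_total = excess + supported,
    ra226 = supported,
    oc_percent = oc), ...)
}

# Minimal dated_profile for unit-formula tests.
fake_dated_profile <- function(df, lake_id = "fake", model = "CRS") {
  structure(df, class = c("dated_profile", "data.frame"),
            lake_id = lake_id, model = model, collection_year = NULL)
}

# Duration-weighted mean of mass accumulation over ages <= window,
# the quantity the burial analysis consumes from a dated core.
window_mean_mar <- function(dated, window = 100) {
  ok <- !is.na(dated$age) & dated$age <= window
  w <- dated$age_bot[ok] - dated$age_top[ok]
  sum(dated$mar[ok] * w) / sum(w)
}
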