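Package: lakeburial
Title: Lead-210 Geochronology and Global Upscaling of Lake Organic-Carbon Burial
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating recent (~50-100 year) organic-carbon burial in
    lake sediments from unsupported lead-210 profiles, and for upscaling such
    rates to biome-stratified regional and global carbon budgets. Implements the
    constant-rate-of-supply (CRS) and constant-initial-concentration (CIC) age
    models, per-interval and whole-lake burial rates with sediment-focusing
    corrections, a biome/land-cover/temperature lake classifier, area-weighted
    flux aggregation with an emission comparison, rectangle-based delta-13C vs
    C:N endmember apportionment of sedimentary organic matter, the regression
    and group-comparison statistics used in such syntheses, and seeded synthetic
    data generators for end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    multcomp
Suggests: testthat (>= 3.0.0), withr, minpack.lm
Config/testthat/edition: 3
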