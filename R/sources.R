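#' Endmember rectangles in (delta-13C, C:N) space
#'
#' Each organic-matter source occupies a characteristic rectangle in the
#' plane spanned by delta-13C (permil vs VPDB) and the molar C:N ratio:
#' phytoplankton is N-rich (low C:N), vascular C3 and C4 plants are N-poor
#' (high C:N) and separated by photosynthetic pathway along the delta-13C
#' axis, and C3-derived soil organic matter sits at intermediate C:N.
#'
#' @param d13c_ranges named list of length-2 numeric ranges (permil).
#' @param cn_ranges named list of length-2 numeric ranges (molar), same
#'   names.
#' @return object of class `endmember_set`: data.frame with columns `source`,
#'   `d13c_min`, `d13c_max`, `cn_min`, `cn_max`.
#' @export
endmember_set <- function(d13c_ranges, cn_ranges) {
  if (!identical(sort(names(d13c_ranges)), sort(names(cn_ranges))))
    stop("d13c_ranges and cn_ranges must use identical source names")
  labels <- names(d13c_ranges)
  if (anyDuplicated(labels)) stop("source labels must be unique")
  df <- do.call(rbind, lapply(labels, function(lab) {
    d <- sort(as.numeric(d13c_ranges[[lab]]))
    cn <- sort(as.numeric(cn_ranges[[lab]]))
    if (length(d) != 2L || length(cn) != 2L || d[1] == d[2] || cn[1] == cn[2])
      stop("ranges must be non-empty intervals (source '", lab, "')")
    data.frame(source = lab, d13c_min = d[1], d13c_max = d[2],
               cn_min = cn[1], cn_max = cn[2])
  }))
  structure(df, class = c("endmember_set", "data.frame"))
}

#' Default endmember set for humid-tropical lake sediments
#'
#' The rectangle boundaries below are literature-informed assumptions, not
#' measurements: typical isotope/stoichiometry envelopes for Amazonian
#' phytoplankton, C3 woody vegetation, C4 grasses and C3-derived soils.
#' Override them with site-appropriate values via [endmember_set()] or
#' [read_endmembers()] for any real interpretation.
#'
#' @return an [endmember_set()].
#' @export
default_endmembers <- function() {
  endmember_set(
    d13c_ranges = list("phytoplankton" = c(-35, -28),
                       "C3 soil" = c(-30, -24),
                       "C3 plants" = c(-35, -26),
                       "C4 plants" = c(-17, -9)),
    cn_ranges = list("phytoplankton" = c(4, 8),
                     "C3 soil" = c(8, 14),
                     "C3 plants" = c(15, 45),
                     "C4 plants" = c(15, 45)))
}

#' Read an endmember set from YAML
#'
#' Expected layout: a top-level `endmembers` map of source name to
#' `d13c: [min, max]` and `cn: [min, max]`.
#'
#' @param path YAML file path.
#' @return an [endmember_set()].
#' @export
read_endmembers <- function(path) {
  y <- yaml::read_yaml(path)
  em <- if (!is.null(y$endmembers)) y$endmembers else y
  endmember_set(lapply(em, function(e) as.numeric(e$d13c)),
                lapply(em, function(e) as.numeric(e$cn)))
}

#' Surface-sediment isotopic signature of a core
#'
#' Thickness-weighted mean delta-13C and C:N over the intervals lying fully
#' within the top of the core (default 0-6 cm), the layer taken to represent
#' recently deposited organic matter.
#'
#' @param core a [core_profile()] with `d13c` and `cn_molar` columns.
#' @param top_cm depth limit (cm, default 6).
#' @return data.frame with one row: `lake_id`, `d13c`, `cn_molar`.
#' @export
surface_signature <- function(core, top_cm = 6) {
  stopifnot(inherits(core, "core_profile"))
  if (is.null(core$d13c) || is.null(core$cn_molar))
    stop("core has no d13c / cn_molar measurements")
  inside <- core$top_depth + core$thickness <= top_cm + 1e-9
  ok <- inside & !is.na(core$d13c) & !is.na(core$cn_molar)
  if (!any(ok)) stop("no isotope data within the top ", top_cm, " cm")
  w <- core$thickness[ok]
  data.frame(lake_id = attr(core, "lake_id"),
             d13c = sum(core$d13c[ok] * w) / sum(w),
             cn_molar = sum(core$cn_molar[ok] * w) / sum(w))
}

#' Apportion sediment signatures among endmember sources
#'
#' Each (delta-13C, C:N) point is assigned to the endmember rectangle that
#' contains it (rectangle edges count as inside). Points inside no rectangle,
#' or inside two or more (ambiguous), are counted as unclassified. Reported
#' contributions are percentages of all samples and sum, together with the
#' unclassified share, to 100.
#'
#' @param signatures data.frame with columns `d13c` and `cn_molar`.
#' @param endmembers an [endmember_set()].
#' @return object of class `source_apportionment`: list with `contributions`
#'   (named % per source), `unclassified_pct`, `n`, `n_ambiguous`, and
#'   `assignment` (character vector of per-sample labels, `NA` for
#'   unclassified).
#' @export
apportion_sources <- function(signatures, endmembers = default_endmembers()) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (!all(c("d13c", "cn_molar") %in% names(signatures)))
    stop("signatures need columns d13c and cn_molar")
  n <- nrow(signatures)
  if (n == 0L) stop("empty signature list")
  inside <- sapply(seq_len(nrow(endmembers)), function(j) {
    e <- endmembers[j, ]
    signatures$d13c >= e$d13c_min & signatures$d13c <= e$d13c_max &
      signatures$cn_molar >= e$cn_min & signatures$cn_molar <= e$cn_max
  })
  inside <- matrix(inside, nrow = n)
  hits <- rowSums(inside)
  assignment <- rep(NA_character_, n)
  one <- hits == 1L
  assignment[one] <- endmembers$source[apply(inside[one, , drop = FALSE], 1, which)]
  contributions <- vapply(endmembers$source, function(lab)
    100 * sum(assignment == lab, na.rm = TRUE) / n, numeric(1))
  structure(list(contributions = contributions,
                 unclassified_pct = 100 * sum(is.na(assignment)) / n,
                 n = n, n_ambiguous = sum(hits > 1L),
                 assignment = assignment),
            class = "source_apportionment")
}

#' @export
print.source_apportionment <- function(x, ...) {
  cat(sprintf("<source_apportionment> n = %d samples\n", x$n))
  for (lab in names(x$contributions))
    cat(sprintf("  %-14s %5.1f %%\n", lab, x$contributions[[lab]]))
  cat(sprintf("  %-14s %5.1f %%", "unclassified", x$unclassified_pct))
  if (x$n_ambiguous > 0)
    cat(sprintf(" (%d ambiguous, in >1 rectangle)", x$n_ambiguous))
  cat("\n")
  invisible(x)
}
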