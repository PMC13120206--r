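#' Classification schemes for pollution and risk indices
#'
#' A `classification_scheme` maps a real-valued index onto ordered grades via
#' strictly increasing breakpoints. Every interval is closed on its upper end:
#' a value exactly equal to a breakpoint takes the lower grade (the "<=,"
#' convention of the standard grading tables).
#'
#' @param breakpoints Strictly increasing numeric vector.
#' @param labels Character vector, one longer than `breakpoints`.
#' @param grades Integer grade codes, same length as `labels`
#'   (defaults to `0:(length(labels) - 1)`).
#' @return A `classification_scheme`.
#' @export
classification_scheme <- function(breakpoints, labels,
                                  grades = seq_along(labels) - 1L) {
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  if (length(labels) != length(breakpoints) + 1L)
    stop("need one more label than breakpoints", call. = FALSE)
  if (length(grades) != length(labels))
    stop("need one grade per label", call. = FALSE)
  structure(list(breakpoints = breakpoints, labels = labels,
                 grades = as.integer(grades)),
            class = "classification_scheme")
}

#' @rdname classification_scheme
#' @param scheme A `classification_scheme`.
#' @param x Numeric vector to classify.
#' @return `classify()` returns a tibble with columns `value`, `grade`,
#'   `label`.
#' @export
classify <- function(scheme, x) {
  stopifnot(inherits(scheme, "classification_scheme"))
  idx <- findInterval(x, scheme$breakpoints, left.open = TRUE) + 1L
  tibble::tibble(value = x, grade = scheme$grades[idx],
                 label = scheme$labels[idx])
}

.contamination_labels <- c(
  "Uncontaminated", "Slightly contaminated", "Moderately contaminated",
  "Moderately to heavily contaminated", "Heavily contaminated",
  "Extremely contaminated")

#' @rdname classification_scheme
#' @export
igeo_scheme <- function() {
  classification_scheme(c(0, 1, 2, 3, 4), .contamination_labels)
}

#' @rdname classification_scheme
#' @export
ef_scheme <- function() {
  labels <- .contamination_labels
  labels[4] <- "Moderately/Heavily contaminated"
  classification_scheme(c(1, 2, 5, 20, 40), labels)
}

#' @rdname classification_scheme
#' @export
ri_scheme <- function() {
  classification_scheme(
    c(150, 300, 600, 1200),
    c("Slight risk", "Moderate risk", "Higher risk", "High risk",
      "Extremely high risk"),
    grades = c(0L, 1L, 2L, 3L, 5L))
}

#' Geo-accumulation index
#'
#' `Igeo = log2(C / (1.5 * C0))`: the measured concentration against 1.5
#' times its geochemical background, on a log2 scale. The factor 1.5 absorbs
#' natural (diagenetic) variation of the background.
#'
#' @param c Measured concentration, mg/kg (> 0).
#' @param c0 Background concentration, mg/kg (> 0).
#' @return Igeo, in log2 units. Vectorized with recycling.
#' @examples
#' igeo(0.17, 0.047)
#' @export
igeo <- function(c, c0) {
  if (any(c <= 0) || any(c0 <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  log2(c / (1.5 * c0))
}

#' @rdname igeo
#' @param x Index values to classify.
#' @return `classify_igeo()` and friends return a tibble `value`/`grade`/`label`.
#' @export
classify_igeo <- function(x) classify(igeo_scheme(), x)

#' Enrichment factor
#'
#' Double ratio of a metal to a conservative reference element (Al) in the
#' sample versus the background:
#' `EF = (Ci/Cref)_sample / (Ci/Cref)_background`. Normalizing by Al corrects
#' for grain-size and mineralogy effects.
#'
#' @param ci Metal concentration in the sample, mg/kg.
#' @param c_ref_sample Reference-element concentration in the sample, mg/kg.
#' @param bg_i Metal background value, mg/kg.
#' @param bg_ref Reference-element background value, mg/kg.
#' @return The enrichment factor. Vectorized with recycling.
#' @export
enrichment_factor <- function(ci, c_ref_sample, bg_i, bg_ref) {
  if (any(ci <= 0) || any(c_ref_sample <= 0) || any(bg_i <= 0) ||
      any(bg_ref <= 0))
    stop("all enrichment-factor inputs must be > 0", call. = FALSE)
  (ci / c_ref_sample) / (bg_i / bg_ref)
}

#' @rdname enrichment_factor
#' @param x Index values to classify.
#' @export
classify_ef <- function(x) classify(ef_scheme(), x)

#' Contamination factor
#'
#' Plain ratio of a measured concentration to its background value.
#'
#' @param ci Measured concentration, mg/kg (> 0).
#' @param cn_i Background concentration, mg/kg (> 0).
#' @return `ci / cn_i`. Vectorized with recycling.
#' @export
contamination_factor <- function(ci, cn_i) {
  if (any(ci <= 0) || any(cn_i <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  ci / cn_i
}

#' Single-metal potential ecological risk
#'
#' Toxicity-weighted contamination measure `Er`. Two forms are provided:
#' * `"paper_division"` (default): `Er = Tr / Cf`. This is the form printed
#'   and numerically used by the study this package reproduces; its published
#'   mean Er values are consistent only with the division.
#' * `"hakanson_product"`: `Er = Tr * Cf`, the canonical Hakanson form from
#'   the wider literature, provided behind this flag.
#'
#' @param cf Contamination factor (> 0).
#' @param tr Toxic-response factor (> 0).
#' @param mode Which form to evaluate.
#' @return Er. Vectorized with recycling.
#' @export
single_metal_risk <- function(cf, tr,
                              mode = c("paper_division", "hakanson_product")) {
  mode <- match.arg(mode)
  if (any(cf <= 0) || any(tr <= 0))
    stop("cf and tr must be > 0", call. = FALSE)
  if (mode == "paper_division") tr / cf else tr * cf
}

#' Comprehensive potential ecological risk index
#'
#' `RI` is the sum of the nine single-metal risks `Er` at one site, graded
#' on the standard five-class scale (slight risk up to 150, extremely high
#' risk above 1200).
#'
#' @param er_values Named numeric vector with one non-negative Er per metal
#'   ([metal_names()]).
#' @return One-row tibble with columns `ri`, `grade`, `label`.
#' @export
risk_index <- function(er_values) {
  missing <- setdiff(metal_names(), names(er_values))
  if (length(missing) > 0)
    stop(sprintf("missing Er for metal(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (any(er_values[metal_names()] < 0))
    stop("Er values must be non-negative", call. = FALSE)
  ri <- sum(er_values[metal_names()])
  cl <- classify(ri_scheme(), ri)
  tibble::tibble(ri = ri, grade = cl$grade, label = cl$label)
}

#' Full deterministic index assessment of a sample table
#'
#' Computes, per site and metal, the geo-accumulation index, contamination
#' factor, single-metal ecological risk and (when an `Al` column is present)
#' the enrichment factor, each with its grade, plus the per-site risk index
#' `RI`.
#'
#' @param table A [sample_table()].
#' @param reference A [reference_table()].
#' @param er_mode Passed to [single_metal_risk()].
#' @return A list of class `pollution_assessment` with `by_metal` (tidy
#'   tibble: site_id, metal, conc, igeo, igeo_grade, igeo_label, cf, er,
#'   ef, ef_grade, ef_label) and `by_site` (site_id, ri, grade, label).
#' @export
assess_pollution <- function(table, reference = default_reference(),
                             er_mode = c("paper_division", "hakanson_product")) {
  er_mode <- match.arg(er_mode)
  has_al <- "Al" %in% names(table)
  if (!has_al)
    warning("no Al column: enrichment factors omitted", call. = FALSE)
  rows <- lapply(metal_names(), function(m) {
    conc <- table[[m]]
    ig <- igeo(conc, reference$background[[m]])
    igc <- classify_igeo(ig)
    cf <- contamination_factor(conc, reference$background[[m]])
    er <- single_metal_risk(cf, reference$toxic_response[[m]], er_mode)
    if (has_al) {
      ef <- enrichment_factor(conc, table$Al, reference$background[[m]],
                              reference$al_background)
      efc <- classify_ef(ef)
    } else {
      ef <- rep(NA_real_, length(conc))
      efc <- tibble::tibble(grade = rep(NA_integer_, length(conc)),
                            label = rep(NA_character_, length(conc)))
    }
    tibble::tibble(site_id = table$site_id, metal = m, conc = conc,
                   igeo = ig, igeo_grade = igc$grade, igeo_label = igc$label,
                   cf = cf, er = er,
                   ef = ef, ef_grade = efc$grade, ef_label = efc$label)
  })
  by_metal <- do.call(rbind, rows)
  er_mat <- matrix(by_metal$er, nrow = nrow(table),
                   dimnames = list(NULL, metal_names()))
  by_site <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    cbind(tibble::tibble(site_id = table$site_id[i]), risk_index(er_mat[i, ]))
  }))
  structure(list(by_metal = by_metal, by_site = tibble::as_tibble(by_site)),
            class = "pollution_assessment")
}
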