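#' The nine metals of the sediment survey
#'
#' Canonical order of the heavy metals handled by the package: As, Cd, Cr,
#' Cu, Hg, Mn, Ni, Pb, Zn (all concentrations in mg/kg dry weight).
#'
#' @return Character vector of length nine.
#' @export
metal_names <- function() c("As", "Cd", "Cr", "Cu", "Hg", "Mn", "Ni", "Pb", "Zn")

.validate_sample_table <- function(df, require_al = FALSE) {
  if (!"site_id" %in% names(df))
    stop("sample table must have a 'site_id' column", call. = FALSE)
  missing <- setdiff(metal_names(), names(df))
  if (length(missing) > 0)
    stop(sprintf("missing metal column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (require_al && !"Al" %in% names(df))
    stop("missing reference-element column: Al", call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("site ids must be unique", call. = FALSE)
  cols <- intersect(c(metal_names(), "Al"), names(df))
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("non-numeric concentration in column %s", col), call. = FALSE)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0)
      stop(sprintf("non-positive concentration at site %s, metal %s",
                   df$site_id[bad[1]], col), call. = FALSE)
  }
  invisible(df)
}

#' Construct a per-site sediment concentration table
#'
#' @param df Data frame with a `site_id` column, one column per metal
#'   ([metal_names()]), optionally `Al` (reference element) and coordinate
#'   columns. Concentrations are mg/kg dry weight and must be strictly
#'   positive.
#' @param require_al Require the `Al` column to be present.
#' @return A `sample_table` (a tibble subclass).
#' @export
sample_table <- function(df, require_al = FALSE) {
  df <- tibble::as_tibble(df)
  .validate_sample_table(df, require_al)
  class(df) <- unique(c("sample_table", class(df)))
  df
}

#' Read / write a sediment sample table as CSV
#'
#' The CSV dialect is comma-separated, dot-decimal, UTF-8, with a header row
#' naming `site_id` and the metal columns. `write_sample_table()` writes
#' numeric columns at 17 significant digits so a round trip reproduces the
#' stored values exactly.
#'
#' @param path Path to a CSV file.
#' @param require_al Require the `Al` reference-element column.
#' @param table A [sample_table()].
#' @return `read_sample_table()` returns a validated [sample_table()] with
#'   row order preserved; `write_sample_table()` returns `path` invisibly.
#' @export
read_sample_table <- function(path, require_al = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  sample_table(df, require_al = require_al)
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-metal summary statistics of a sample table
#'
#' Computes min, max, median, mean, standard deviation (sample, `n - 1`
#' denominator) and coefficient of variation (percent) for each metal.
#'
#' @param table A [sample_table()] with at least 2 rows.
#' @return A tibble with one row per metal and columns `metal`, `min`, `max`,
#'   `median`, `mean`, `sd`, `cv`.
#' @export
summarize_samples <- function(table) {
  if (nrow(table) < 2)
    stop("need at least 2 rows (sd undefined otherwise)", call. = FALSE)
  rows <- lapply(metal_names(), function(m) {
    v <- table[[m]]
    mu <- mean(v); s <- stats::sd(v)
    tibble::tibble(metal = m, min = min(v), max = max(v),
                   median = stats::median(v), mean = mu, sd = s,
                   cv = 100 * s / mu)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of metal concentrations
#'
#' @param table A [sample_table()] with at least 3 rows and no constant
#'   metal column.
#' @param method Correlation method; only `"pearson"` is supported.
#' @return Symmetric matrix with unit diagonal, one row/column per metal.
#' @export
correlation_matrix <- function(table, method = "pearson") {
  method <- match.arg(method)
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  x <- as.matrix(table[, metal_names()])
  const <- metal_names()[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(const) > 0)
    stop(sprintf("constant column(s): %s", paste(const, collapse = ", ")),
         call. = FALSE)
  r <- stats::cor(x, method = method)
  diag(r) <- 1
  r
}

#' Geochemical background values and toxic-response factors
#'
#' Reference constants for the pollution and ecological-risk indices. The
#' defaults are the Dongting Lake water-system background values (mg/kg) and
#' the standard toxic-response factors (As 10, Cd 30, Cr 2, Cu 5, Pb 5, Zn 1,
#' Mn 1, Ni 5, Hg 40). The Al background is a nominal crustal value — the
#' enrichment factor depends only on the sample/background Al ratio, so its
#' absolute level cancels.
#'
#' @param background Named numeric vector of background values, mg/kg, one
#'   entry per metal.
#' @param toxic_response Named numeric vector of toxic-response factors.
#' @param al_background Reference-element (Al) background, mg/kg.
#' @return A `reference_table` list with elements `background`,
#'   `toxic_response`, `al_background`.
#' @export
reference_table <- function(background, toxic_response, al_background = 70000) {
  for (nm in list(background, toxic_response)) {
    missing <- setdiff(metal_names(), names(nm))
    if (length(missing) > 0)
      stop(sprintf("reference values missing for: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    if (any(nm[metal_names()] <= 0))
      stop("reference values must be > 0", call. = FALSE)
  }
  structure(list(background = background[metal_names()],
                 toxic_response = toxic_response[metal_names()],
                 al_background = al_background),
            class = "reference_table")
}

#' @rdname reference_table
#' @export
default_reference <- function() {
  reference_table(
    background = c(As = 12.90, Cd = 0.33, Cr = 44.00, Cu = 20.20, Hg = 0.047,
                   Mn = 450.00, Ni = 21.20, Pb = 23.30, Zn = 83.30),
    toxic_response = c(As = 10, Cd = 30, Cr = 2, Cu = 5, Hg = 40,
                       Mn = 1, Ni = 5, Pb = 5, Zn = 1)
  )
}

#' Route-specific toxicology constants for the health-risk model
#'
#' Reference doses (RfD, mg/(kg·d)) and carcinogenic slope factors
#' (SF, (mg/(kg·d))^-1) per metal and exposure route, plus dermal absorption
#' fractions (ABS). SF entries are `NA` where no slope factor is established
#' (ingestion: all but As/Cd/Cr/Pb; dermal: all but As/Cd) — carcinogenic
#' risk is simply not computed there.
#'
#' @return A `toxicology_table` list with named numeric vectors `rfd_ing`,
#'   `rfd_derm`, `sf_ing`, `sf_derm`, `abs_dermal`.
#' @export
default_toxicology <- function() {
  structure(list(
    rfd_ing = c(As = 3.00e-4, Cd = 1.00e-3, Cr = 3.00e-3, Cu = 4.00e-2,
                Hg = 3.00e-4, Mn = 4.60e-2, Ni = 2.00e-2, Pb = 3.50e-3,
                Zn = 3.50e-1),
    rfd_derm = c(As = 1.23e-4, Cd = 1.00e-5, Cr = 6.00e-5, Cu = 1.20e-2,
                 Hg = 2.10e-5, Mn = 1.84e-3, Ni = 5.40e-3, Pb = 5.25e-3,
                 Zn = 6.00e-2),
    sf_ing = c(As = 1.50, Cd = 1.80, Cr = 0.50, Cu = NA, Hg = NA,
               Mn = NA, Ni = NA, Pb = 8.50e-3, Zn = NA),
    sf_derm = c(As = 1.50, Cd = 0.38, Cr = NA, Cu = NA, Hg = NA,
                Mn = NA, Ni = NA, Pb = NA, Zn = NA),
    abs_dermal = c(As = 0.03, Cd = 0.14, Cr = 0.001, Cu = 0.1, Hg = 0.50,
                   Mn = 0.01, Ni = 0.35, Pb = 0.006, Zn = 0.02)
  ), class = "toxicology_table")
}
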