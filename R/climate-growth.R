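#' Month labels of the dendroclimatic window
#' @keywords internal
window_months <- function(window_end = c("C_Sep", "C_Oct")) {
  window_end <- match.arg(window_end)
  prev <- paste0("P_", month.abb[10:12])
  cur <- paste0("C_", month.abb[1:ifelse(window_end == "C_Sep", 9, 10)])
  c(prev, cur)
}

#' Align monthly climate predictors with ring years
#'
#' Builds the design table for climate-growth correlations: for each ring
#' year `Y` the row holds every requested climate variable at the months of
#' the dendroclimatic window, previous October (`P_Oct`, i.e. October of
#' `Y - 1`) through current September (`C_Sep`), or through current October
#' when `window_end = "C_Oct"`.
#'
#' @param climate Monthly climate data frame (see [derive_climate()] for the
#'   derived columns).
#' @param years Ring (chronology) years.
#' @param vars Climate columns to lag-align.
#' @param window_end `"C_Sep"` (default) or `"C_Oct"`.
#' @return Data frame with a `year` column and one column per
#'   variable-month cell, named `<var>.<label>`; rows with any missing month
#'   are dropped.
#' @export
lag_align <- function(climate, years,
                      vars = intersect(c("prcp_mm", "tmean_c", "tmax_c", "tmin_c",
                                         "rh_pct", "vpd_kpa", "spei1"),
                                       names(climate)),
                      window_end = "C_Sep") {
  labels <- window_months(window_end)
  if (!length(vars)) stop("no climate variables to align", call. = FALSE)
  need_min <- min(years) - 1
  if (!any(climate$year == need_min & climate$month == 10)) {
    stop("climate must start no later than October of ", need_min,
         " (one year before the first ring year)", call. = FALSE)
  }
  key <- climate$year * 12 + climate$month
  mon_no <- c(10:12, 1:10)[seq_along(labels)]
  yr_off <- c(rep(-1, 3), rep(0, length(labels) - 3))

  out <- data.frame(year = years)
  for (v in vars) {
    for (k in seq_along(labels)) {
      idx <- match((years + yr_off[k]) * 12 + mon_no[k], key)
      out[[paste(v, labels[k], sep = ".")]] <- climate[[v]][idx]
    }
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (!nrow(out)) stop("no ring years with complete climate coverage", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Monthly climate-growth Pearson correlations
#'
#' Correlates a chronology index with every variable-month cell of the
#' lag-aligned design table; p-values come from the exact t distribution.
#' Stars follow the usual convention (`*` p < 0.05, `**` p < 0.01); no
#' multiple-testing correction is applied, matching per-cell significance
#' screens, so expect about 5 percent false positives among null cells.
#'
#' @param chronology A `chronology` object or a data frame with `year` and
#'   `index`.
#' @param design Output of [lag_align()].
#' @param min_years Minimum overlapping years (default 15).
#' @return Long data frame `variable`, `month`, `r`, `p`, `n`, `flag`.
#' @export
correlate_climate_growth <- function(chronology, design, min_years = 15) {
  chron <- if (inherits(chronology, "chronology")) chronology$data else chronology
  stopifnot(all(c("year", "index") %in% names(chron)))
  idx <- chron$index[match(design$year, chron$year)]
  ok <- !is.na(idx)
  if (sum(ok) < min_years) {
    stop("fewer than ", min_years, " overlapping years", call. = FALSE)
  }
  idx <- idx[ok]
  design <- design[ok, , drop = FALSE]

  cells <- setdiff(names(design), "year")
  parts <- strsplit(cells, ".", fixed = TRUE)
  res <- lapply(seq_along(cells), function(i) {
    x <- design[[cells[i]]]
    if (stats::sd(x) == 0) {
      return(data.frame(variable = parts[[i]][1], month = parts[[i]][2],
                        r = NA_real_, p = NA_real_, n = length(x), flag = "zero_var"))
    }
    ct <- stats::cor.test(idx, x, method = "pearson")
    p <- ct$p.value
    data.frame(variable = parts[[i]][1], month = parts[[i]][2],
               r = unname(ct$estimate), p = p, n = length(x),
               flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the most significant climate factors
#'
#' Ranks significant cells of a correlation table by absolute correlation
#' (ties broken by window month order) and returns the top `top_m` for the
#' attribution stage.
#'
#' @param table Output of [correlate_climate_growth()].
#' @param alpha Significance level (default 0.05).
#' @param top_m Number of factors returned (default 4).
#' @return The selected rows, strongest first; zero rows (with a warning)
#'   when nothing is significant.
#' @export
select_significant <- function(table, alpha = 0.05, top_m = 4) {
  sig <- table[!is.na(table$p) & table$p < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no climate factor significant at alpha = ", alpha, call. = FALSE)
    return(sig)
  }
  month_rank <- match(sig$month, window_months("C_Oct"))
  sig <- sig[order(-abs(sig$r), month_rank), , drop = FALSE]
  utils::head(sig, top_m)
}
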