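#' Basal area increment from ring-width series
#'
#' Converts per-core radial widths (mm) to per-tree annual basal area
#' increments (cm^2). When a tree has two cores their widths are averaged
#' year by year into one tree-level series first; the radius is accumulated
#' from `r0_mm` (pith offset, default 0) and
#' `BAI_t = pi * (r_t^2 - r_(t-1)^2)`.
#'
#' @param rings Long data frame with columns `core_id`, `tree_id`, `year`,
#'   `width_mm` (and optionally `plot_id`).
#' @param r0_mm Pith offset added to the innermost radius, mm.
#' @return Data frame `tree_id`, `year`, `bai_cm2` (plus `plot_id` when
#'   present in the input).
#' @examples
#' r <- data.frame(core_id = "a", tree_id = "t1", year = 2000:2001,
#'                 width_mm = c(10, 10))
#' bai_from_rings(r)$bai_cm2  # pi, 3*pi
#' @export
bai_from_rings <- function(rings, r0_mm = 0) {
  check_rings_frame(rings)
  out <- lapply(split(rings, rings$tree_id), function(tr) {
    cores <- split(tr, tr$core_id)
    if (length(cores) > 2) {
      stop("more than two cores for tree ", tr$tree_id[1], call. = FALSE)
    }
    if (length(cores) == 2) {
      s1 <- range(cores[[1]]$year)
      s2 <- range(cores[[2]]$year)
      if (s1[2] < s2[1] || s2[2] < s1[1]) {
        stop("cores of tree ", tr$tree_id[1],
             " have non-overlapping year ranges", call. = FALSE)
      }
    }
    w <- tapply(tr$width_mm, tr$year, mean)
    yrs <- as.integer(names(w))
    r_mm <- r0_mm + cumsum(as.numeric(w))
    r_prev <- c(r0_mm, r_mm[-length(r_mm)])
    d <- data.frame(tree_id = tr$tree_id[1], year = yrs,
                    bai_cm2 = pi * (r_mm^2 - r_prev^2) / 100)
    if ("plot_id" %in% names(tr)) d$plot_id <- tr$plot_id[1]
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$tree_id, out$year), , drop = FALSE]
}

#' Regional curve standardization (RCS) detrending
#'
#' The regional curve is the mean ring width at each cambial age across all
#' cores of a site, smoothed with a cubic smoothing spline; each measured
#' width is divided by the curve value at its age, giving dimensionless
#' ratio indices. Cambial age is `year - planting_year + 1` (even-aged
#' plantation, pith at planting).
#'
#' @param rings Long ring-width data frame (`core_id`, `tree_id`, `year`,
#'   `width_mm`).
#' @param planting_year Calendar year of planting (single value for the site).
#' @param stiffness Spline stiffness as a fraction of the maximum cambial age;
#'   the equivalent degrees of freedom are `max(4, round(n_ages * stiffness))`.
#' @param min_cores Minimum number of cores required (default 5).
#' @return Long data frame `core_id`, `tree_id`, `year`, `age`, `index`, with
#'   the fitted regional curve attached as `attr(, "regional_curve")`
#'   (data frame `age`, `width_mm`).
#' @export
rcs_detrend <- function(rings, planting_year, stiffness = 0.10, min_cores = 5) {
  check_rings_frame(rings)
  if (length(unique(rings$core_id)) < min_cores) {
    stop("RCS needs at least ", min_cores, " cores", call. = FALSE)
  }
  age <- rings$year - planting_year + 1
  if (any(age < 1)) stop("rings dated before the planting year", call. = FALSE)

  mean_w <- tapply(rings$width_mm, age, mean)
  ages <- as.integer(names(mean_w))
  used <- seq.int(min(ages), max(ages))
  if (!all(used %in% ages)) {
    stop("cambial ages with zero sample depth inside the used range",
         call. = FALSE)
  }
  n_ages <- length(ages)
  df <- max(4, round(n_ages * stiffness))
  df <- min(df, n_ages - 1)
  if (n_ages > 4) {
    sp <- stats::smooth.spline(ages, as.numeric(mean_w), df = df)
    curve <- stats::predict(sp, ages)$y
  } else {
    curve <- as.numeric(mean_w)
  }
  curve <- pmax(curve, 1e-3)  # guard against non-positive spline excursions

  idx <- rings$width_mm / curve[match(age, ages)]
  out <- data.frame(core_id = rings$core_id, tree_id = rings$tree_id,
                    year = rings$year, age = age, index = idx)
  attr(out, "regional_curve") <- data.frame(age = ages, width_mm = curve)
  out
}

#' Autoregressive prewhitening of an index series
#'
#' Fits an AR(p) model with the order chosen by AIC (0..`max_order`) and
#' returns the residuals re-centred to mean 1, as used for residual
#' chronologies. Order 0 (white noise preferred) returns the series
#' unchanged; the first `p` values of an AR(p) residual series are `NA`.
#'
#' @param x Numeric index series, length >= 20.
#' @param max_order Maximum AR order considered (default 3).
#' @return Numeric series of the same length.
#' @export
ar_prewhiten <- function(x, max_order = 3) {
  if (length(x) < 20) stop("series too short to prewhiten (need >= 20)", call. = FALSE)
  if (stats::sd(x, na.rm = TRUE) == 0) return(x)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = max_order, method = "yule-walker",
              na.action = stats::na.fail),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$order == 0) return(x)
  res <- as.numeric(fit$resid)
  res - mean(res, na.rm = TRUE) + 1
}

#' Build a site chronology with quality statistics
#'
#' Averages residual core indices into a yearly chronology (arithmetic mean,
#' or Tukey biweight robust mean behind a flag) and computes the classical
#' signal statistics: `rbar` (mean pairwise interseries correlation over
#' common periods), and the Wigley quantities
#' `EPS = n rbar / (n rbar + (1 - rbar))` and `SNR = n rbar / (1 - rbar)`
#' with `n` the mean sample depth.
#'
#' @param index Long data frame `core_id`, `year`, `index` (typically the
#'   output of [rcs_detrend()] after [ar_prewhiten()] per core).
#' @param min_overlap Minimum overlapping years for a core pair to enter
#'   `rbar` (default 10).
#' @param biweight Use a Tukey biweight robust mean instead of the arithmetic
#'   mean (default `FALSE`).
#' @return Object of class `chronology`: list with `data` (`year`, `index`,
#'   `depth`), `rbar`, `eps`, `snr`, `n_eff`.
#' @export
build_chronology <- function(index, min_overlap = 10, biweight = FALSE) {
  stopifnot(all(c("core_id", "year", "index") %in% names(index)))
  years <- sort(unique(index$year))
  cores <- unique(as.character(index$core_id))
  wide <- matrix(NA_real_, length(years), length(cores),
                 dimnames = list(years, cores))
  wide[cbind(match(index$year, years), match(as.character(index$core_id), cores))] <-
    index$index
  if (ncol(wide) < 2) stop("need at least two cores", call. = FALSE)

  depth <- rowSums(!is.na(wide))
  mean_fun <- if (biweight) tukey_biweight_mean else function(v) mean(v, na.rm = TRUE)
  chron <- apply(wide, 1, function(v) mean_fun(v[!is.na(v)]))
  years <- as.integer(rownames(wide))

  # mean pairwise correlation over common periods
  cors <- c()
  nc <- ncol(wide)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      ok <- !is.na(wide[, i]) & !is.na(wide[, j])
      if (sum(ok) >= min_overlap &&
          stats::sd(wide[ok, i]) > 0 && stats::sd(wide[ok, j]) > 0) {
        cors <- c(cors, stats::cor(wide[ok, i], wide[ok, j]))
      }
    }
  }
  if (length(cors) == 0) stop("no core pairs with sufficient overlap", call. = FALSE)
  rbar <- mean(cors)
  n_eff <- mean(depth[depth > 0])
  eps <- wigley_eps(n_eff, rbar)
  snr <- wigley_snr(n_eff, rbar)

  out <- list(data = data.frame(year = years, index = unname(chron),
                                depth = unname(depth)),
              rbar = rbar, eps = eps, snr = snr, n_eff = n_eff)
  class(out) <- "chronology"
  out
}

#' @export
print.chronology <- function(x, ...) {
  cat("Tree-ring chronology:", nrow(x$data), "years,",
      sprintf("mean depth %.1f\n", x$n_eff))
  cat(sprintf("  Rbar = %.3f, EPS = %.3f, SNR = %.2f\n", x$rbar, x$eps, x$snr))
  invisible(x)
}

#' Wigley expressed population signal and signal-to-noise ratio
#'
#' `EPS = n rbar / (n rbar + (1 - rbar))`, `SNR = n rbar / (1 - rbar)`;
#' the two are linked by `EPS = SNR / (1 + SNR)`.
#'
#' @param n (mean) sample depth.
#' @param rbar Mean interseries correlation.
#' @return The statistic.
#' @export
wigley_eps <- function(n, rbar) n * rbar / (n * rbar + (1 - rbar))

#' @rdname wigley_eps
#' @export
wigley_snr <- function(n, rbar) n * rbar / (1 - rbar)

#' @rdname wigley_eps
#' @param snr Signal-to-noise ratio.
#' @export
eps_from_snr <- function(snr) snr / (1 + snr)

#' @rdname wigley_eps
#' @param eps Expressed population signal.
#' @export
snr_from_eps <- function(eps) eps / (1 - eps)

# Tukey biweight robust mean (one-step iterated), c = 9
tukey_biweight_mean <- function(v, c = 9, tol = 1e-8, max_iter = 50) {
  m <- stats::median(v)
  for (i in seq_len(max_iter)) {
    s <- stats::median(abs(v - m))
    if (s < tol) return(m)
    u <- (v - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m_new <- sum(w * v) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Select cores covering a common time span
#'
#' Keeps cores whose span covers the inter-quartile common period of all
#' cores, so growth comparisons use cores of the same time span.
#'
#' @param rings Long ring-width data frame.
#' @return The filtered data frame.
#' @export
common_span_filter <- function(rings) {
  check_rings_frame(rings)
  firsts <- tapply(rings$year, rings$core_id, min)
  lasts <- tapply(rings$year, rings$core_id, max)
  lo <- stats::quantile(firsts, 0.75, type = 1)
  hi <- stats::quantile(lasts, 0.25, type = 1)
  keep <- names(firsts)[firsts <= lo & lasts >= hi]
  rings[rings$core_id %in% keep, , drop = FALSE]
}

check_rings_frame <- function(rings) {
  need <- c("core_id", "tree_id", "year", "width_mm")
  missing <- setdiff(need, names(rings))
  if (length(missing)) {
    stop("ring table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(rings$width_mm <= 0)) stop("ring widths must be positive", call. = FALSE)
  bad <- vapply(split(rings$year, rings$core_id),
                function(y) any(diff(sort(y)) != 1), logical(1))
  if (any(bad)) {
    stop("non-contiguous years in core(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
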