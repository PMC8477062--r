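#' Saturation vapour pressure (Magnus formula)
#'
#' @param temperature Air temperature, degrees C.
#' @return Saturation vapour pressure, kPa.
#' @keywords internal
saturation_vp <- function(temperature) {
  0.6108 * exp(17.27 * temperature / (temperature + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD is the difference between the saturation vapour pressure at air
#' temperature and the actual vapour pressure, `e_s(T) * (1 - RH/100)`.
#' Saturation vapour pressure uses the Magnus formula
#' `0.6108 * exp(17.27 T / (T + 237.3))` kPa.
#'
#' @param temperature Air temperature, degrees C. Vectorised.
#' @param rel_humidity Relative humidity, percent, in `(0, 100]`.
#' @return VPD in kPa, same length as the inputs.
#' @examples
#' vpd_from_t_rh(25, 50)   # about 1.58 kPa
#' vpd_from_t_rh(25, 100)  # saturated air: 0
#' @export
vpd_from_t_rh <- function(temperature, rel_humidity) {
  if (any(!is.finite(rel_humidity)) || any(rel_humidity <= 0) ||
      any(rel_humidity > 100)) {
    stop("`rel_humidity` must lie in (0, 100]", call. = FALSE)
  }
  saturation_vp(temperature) * (1 - rel_humidity / 100)
}

# mid-month Julian day and day count, non-leap calendar
.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_mid_julian <- cumsum(.month_days) - .month_days / 2

#' Mean day length per calendar month
#'
#' Astronomical day length (hours) at mid-month from the solar declination
#' and sunset hour angle.
#'
#' @param latitude Latitude in decimal degrees, within `[-66, 66]`.
#' @return Numeric vector of 12 mean day lengths, hours.
#' @keywords internal
month_day_length <- function(latitude) {
  if (!is.finite(latitude) || abs(latitude) > 66) {
    stop("`latitude` must lie within [-66, 66] degrees", call. = FALSE)
  }
  phi <- latitude * pi / 180
  delta <- 0.4093 * sin(2 * pi * .month_mid_julian / 365 - 1.405)
  omega <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 * omega / pi
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical temperature-based PET with day-length correction. The annual
#' heat index is computed from the record's climatological monthly mean
#' temperatures, so a given calendar month's coefficient is constant across
#' years. PET is zero for months with mean temperature at or below 0 degrees C;
#' months above 26.5 degrees C use the standard high-temperature polynomial.
#'
#' @param climate Data frame with columns `year`, `month`, `tmean_c`
#'   (contiguous months, at least 12).
#' @param latitude Latitude in decimal degrees within `[-66, 66]`. If `NULL`,
#'   taken from `attr(climate, "latitude")`.
#' @return Numeric vector of monthly PET, mm, aligned with the rows of
#'   `climate`.
#' @export
pet_thornthwaite <- function(climate, latitude = NULL) {
  if (is.null(latitude)) latitude <- attr(climate, "latitude")
  if (is.null(latitude)) stop("latitude required for Thornthwaite PET", call. = FALSE)
  check_climate_frame(climate, c("year", "month", "tmean_c"))
  if (nrow(climate) < 12) stop("need at least 12 contiguous months", call. = FALSE)

  tmean <- climate$tmean_c
  m <- climate$month
  # climatological heat index from monthly normals
  norm <- vapply(1:12, function(mm) mean(tmean[m == mm]), numeric(1))
  I <- sum(pmax(norm, 0)[norm > 0]^1.514 / 5^1.514)
  if (I <= 0) return(rep(0, length(tmean)))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239

  L <- month_day_length(latitude)
  K <- (L[m] / 12) * (.month_days[m] / 30)

  pet <- numeric(length(tmean))
  cold <- tmean <= 0
  hot <- tmean >= 26.5
  mid <- !cold & !hot
  pet[mid] <- 16 * K[mid] * (10 * tmean[mid] / I)^a
  pet[hot] <- K[hot] * (-415.85 + 32.24 * tmean[hot] - 0.43 * tmean[hot]^2)
  pet
}

#' Fit a three-parameter log-logistic distribution by probability-weighted
#' moments
#'
#' Unbiased PWM estimators (Hosking) give the first three L-moments, which
#' are mapped to the generalized-logistic parameterisation of the
#' log-logistic family, `F(x) = 1 / (1 + exp(-y))` with
#' `y = -log(1 - k (x - xi) / alpha) / k` (the classical log-logistic
#' `F(x) = (1 + (alpha/(x - gamma))^beta)^(-1)` is the `k < 0` branch with
#' `beta = -1/k`). The shape sign follows the sample's L-skewness, so both
#' wet- and drought-skewed balance samples are standardized.
#'
#' @param x Numeric sample (the climatic water balance values).
#' @return List with `xi` (location), `alpha` (scale), `k` (shape), or
#'   `NULL` when the sample is degenerate.
#' @keywords internal
fit_loglogistic_pwm <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(NULL)
  xs <- sort(x)
  j <- seq_len(n)
  # unbiased PWMs b_r = mean( C(j-1, r)/C(n-1, r) x_(j) ), ascending order
  b0 <- mean(xs)
  b1 <- sum((j - 1) / (n - 1) * xs) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * xs) / n
  l1 <- b0
  l2 <- 2 * b1 - b0
  l3 <- 6 * b2 - 6 * b1 + b0
  if (l2 <= 0) return(NULL)
  t3 <- l3 / l2
  if (abs(t3) >= 0.95) return(NULL)
  k <- -t3
  if (abs(k) < 1e-8) {
    # symmetric limit: plain logistic
    return(list(xi = l1, alpha = l2, k = 0))
  }
  gk <- pi * k / sin(pi * k)       # = Gamma(1+k) Gamma(1-k)
  alpha <- l2 / gk
  xi <- l1 - alpha * (1 / k - gk / k)
  list(xi = xi, alpha = alpha, k = k)
}

#' Log-logistic (generalized-logistic) cumulative probability
#' @keywords internal
loglogistic_cdf <- function(x, par) {
  z <- (x - par$xi) / par$alpha
  if (par$k == 0) {
    y <- z
  } else {
    arg <- 1 - par$k * z
    y <- ifelse(arg > 0, -log(arg) / par$k,
                ifelse(par$k < 0, -Inf, Inf))
  }
  p <- 1 / (1 + exp(-y))
  # keep probabilities strictly inside (0,1) so the normal quantile is finite
  pmin(pmax(p, 1e-8), 1 - 1e-8)
}

standardize_loglogistic <- function(values) {
  fit <- fit_loglogistic_pwm(values)
  if (is.null(fit)) return(rep(NA_real_, length(values)))
  stats::qnorm(loglogistic_cdf(values, fit))
}

#' Standardized precipitation-evapotranspiration index
#'
#' The climatic water balance `D = P - PET` is summed over backward windows of
#' `scale_k` months; for each calendar month the windowed sums are fitted with
#' a three-parameter log-logistic distribution by unbiased probability-weighted
#' moments, and cumulative probabilities are mapped to standard normal
#' deviates. The first `scale_k - 1` months, and calendar months with a
#' degenerate (constant) balance, are `NA`.
#'
#' @param climate Data frame with contiguous monthly rows `year`, `month`,
#'   `prcp_mm` and either a `pet_mm` column or `tmean_c` plus a latitude (see
#'   [pet_thornthwaite()]).
#' @param scale_k Aggregation window in months, `>= 1`.
#' @param latitude Passed to [pet_thornthwaite()] when `pet_mm` is absent.
#' @return `climate` with an added column `spei<k>` (e.g. `spei1`, `spei12`).
#' @export
spei <- function(climate, scale_k = 1, latitude = NULL) {
  check_climate_frame(climate, c("year", "month", "prcp_mm"))
  if (scale_k < 1) stop("`scale_k` must be >= 1", call. = FALSE)
  if (any(climate$prcp_mm < 0, na.rm = TRUE)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  if (!"pet_mm" %in% names(climate)) {
    climate$pet_mm <- pet_thornthwaite(climate, latitude)
  }
  d <- climate$prcp_mm - climate$pet_mm
  dk <- as.numeric(stats::filter(d, rep(1, scale_k), sides = 1))

  out <- rep(NA_real_, nrow(climate))
  for (mm in 1:12) {
    idx <- which(climate$month == mm & !is.na(dk))
    if (length(idx) == 0) next
    out[idx] <- standardize_loglogistic(dk[idx])
  }
  climate[[paste0("spei", scale_k)]] <- out
  climate
}

#' Growing-season SPEI (one value per year)
#'
#' The seven-month April-October water balance is summed once per year and the
#' yearly sums are standardized with a log-logistic distribution fitted across
#' years, so each year contributes exactly one growing-season value.
#'
#' @inheritParams spei
#' @param months Growing-season months (default April through October).
#' @return Data frame with `year` and `spei_gs`; years with incomplete
#'   coverage of the season are omitted.
#' @export
growing_season_spei <- function(climate, latitude = NULL, months = 4:10) {
  check_climate_frame(climate, c("year", "month", "prcp_mm"))
  if (!"pet_mm" %in% names(climate)) {
    climate$pet_mm <- pet_thornthwaite(climate, latitude)
  }
  gs <- climate[climate$month %in% months, , drop = FALSE]
  cnt <- tapply(gs$month, gs$year, length)
  full <- as.integer(names(cnt)[cnt == length(months)])
  gs <- gs[gs$year %in% full, , drop = FALSE]
  if (length(full) < 4) stop("too few complete growing seasons", call. = FALSE)
  d <- tapply(gs$prcp_mm - gs$pet_mm, gs$year, sum)
  yrs <- as.integer(names(d))
  data.frame(year = yrs, spei_gs = standardize_loglogistic(as.numeric(d)))
}

#' Mann-Kendall trend test
#'
#' Non-parametric monotone-trend test: `S` is the signed count of concordant
#' minus discordant pairs, its variance is tie-corrected, and the
#' continuity-corrected statistic is referred to the standard normal.
#'
#' @param x Numeric series, `n >= 8` recommended.
#' @param alpha Significance level used to label the `direction`.
#' @return List of class `mk_test` with `s`, `var_s`, `z`, `p`, `n`,
#'   `direction` (one of `"increasing"`, `"decreasing"`, `"none"`).
#' @examples
#' mann_kendall(1:10)  # S = 45, strongly increasing
#' @export
mann_kendall <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("series too short for Mann-Kendall test", call. = FALSE)
  sg <- sign(outer(x, x, "-"))
  s <- sum(sg[lower.tri(sg)])  # sum over i<j of sign(x_j - x_i)

  ties <- table(x)
  t <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  if (var_s <= 0) {
    res <- list(s = 0, var_s = 0, z = 0, p = 1, n = n, direction = "none")
    class(res) <- "mk_test"
    return(res)
  }
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (p < alpha) {
    if (s > 0) "increasing" else "decreasing"
  } else "none"
  res <- list(s = s, var_s = var_s, z = z, p = p, n = n, direction = direction)
  class(res) <- "mk_test"
  res
}

#' @export
print.mk_test <- function(x, ...) {
  cat("Mann-Kendall trend test\n")
  cat(sprintf("  n = %d, S = %d, z = %.3f, p = %.4g, trend: %s\n",
              x$n, x$s, x$z, x$p, x$direction))
  invisible(x)
}

#' Double-mass homogeneity screen
#'
#' Plots (numerically) the cumulative sum of a candidate series against the
#' cumulative sum of a reference, fits the best two-segment linear model over
#' all interior breakpoints, and flags inhomogeneity when the two segment
#' slopes differ by more than `threshold` (relative).
#'
#' @param x Candidate series.
#' @param reference Reference series of equal length.
#' @param threshold Relative slope-ratio deviation that triggers a flag
#'   (default 0.10, i.e. 10 percent).
#' @return List with `break_index`, `slope1`, `slope2`, `ratio`,
#'   `inhomogeneous`.
#' @export
double_mass <- function(x, reference, threshold = 0.10) {
  if (length(x) != length(reference)) stop("series lengths differ", call. = FALSE)
  if (stats::sd(reference) == 0 && sum(reference) == 0) {
    stop("reference series has zero cumulative variance", call. = FALSE)
  }
  cx <- cumsum(x)
  cr <- cumsum(reference)
  n <- length(cx)
  if (n < 6) stop("series too short for a two-segment fit", call. = FALSE)

  best <- NULL
  for (b in 3:(n - 2)) {
    i1 <- 1:b
    i2 <- b:n
    f1 <- stats::lm.fit(cbind(1, cr[i1]), cx[i1])
    f2 <- stats::lm.fit(cbind(1, cr[i2]), cx[i2])
    rss <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, b = b,
                   s1 = unname(f1$coefficients[2]),
                   s2 = unname(f2$coefficients[2]))
    }
  }
  ratio <- best$s2 / best$s1
  list(break_index = best$b, slope1 = best$s1, slope2 = best$s2,
       ratio = ratio, inhomogeneous = is.finite(ratio) && abs(ratio - 1) > threshold)
}

#' Derive standard climate covariates
#'
#' Adds vapour pressure deficit, Thornthwaite PET and SPEI at the 1- and
#' 12-month scales to a monthly climate table.
#'
#' @inheritParams spei
#' @param scales SPEI timescales to add (months).
#' @return The climate data frame with `vpd_kpa`, `pet_mm` and one `spei<k>`
#'   column per requested scale.
#' @export
derive_climate <- function(climate, latitude = NULL, scales = c(1, 12)) {
  check_climate_frame(climate, c("year", "month", "tmean_c", "prcp_mm", "rh_pct"))
  climate$vpd_kpa <- vpd_from_t_rh(climate$tmean_c, climate$rh_pct)
  if (!"pet_mm" %in% names(climate)) {
    climate$pet_mm <- pet_thornthwaite(climate, latitude)
  }
  for (k in scales) climate <- spei(climate, k, latitude)
  climate
}

# shared input validation for monthly climate frames
check_climate_frame <- function(climate, cols) {
  missing <- setdiff(cols, names(climate))
  if (length(missing)) {
    stop("climate table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(climate) > 1) {
    code <- climate$year * 12 + climate$month
    if (any(diff(code) != 1)) {
      stop("climate months must be contiguous with no gaps", call. = FALSE)
    }
  }
  if ("rh_pct" %in% cols &&
      (any(climate$rh_pct <= 0) || any(climate$rh_pct > 100))) {
    stop("relative humidity must lie in (0, 100]", call. = FALSE)
  }
  invisible(TRUE)
}
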