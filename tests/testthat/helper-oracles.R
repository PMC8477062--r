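# Independent oracles used across tests. These are deliberately written as
# plain, slow reference implementations, separate from the package code paths.

# O(n^2) Hegyi reference: explicit double loop
brute_hegyi <- function(stand, radius = 8) {
  n <- nrow(stand)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt((stand$x_m[i] - stand$x_m[j])^2 +
                    (stand$y_m[i] - stand$y_m[j])^2)
      if (dij <= radius) acc <- acc + (stand$dbh_cm[j] / stand$dbh_cm[i]) / dij
    }
    ci[i] <- acc
  }
  ci
}

# annulus-area reference for BAI (mm widths -> cm^2)
brute_bai <- function(widths_mm, r0_mm = 0) {
  r <- r0_mm
  out <- numeric(length(widths_mm))
  for (k in seq_along(widths_mm)) {
    r_new <- r + widths_mm[k]
    out[k] <- (pi * r_new^2 - pi * r^2) / 100
    r <- r_new
  }
  out
}

# textbook Thornthwaite reference, written independently of the package:
# heat index from climatological monthly normals, day length from solar
# declination at mid-month
brute_thornthwaite <- function(tmean, month, latitude) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  jday <- c(15.5, 45, 74.5, 105, 135.5, 166, 196.5, 227.5, 258, 288.5, 319, 349.5)
  normals <- sapply(1:12, function(m) mean(tmean[month == m]))
  I <- 0
  for (m in 1:12) if (normals[m] > 0) I <- I + (normals[m] / 5)^1.514
  a <- 675e-9 * I^3 - 771e-7 * I^2 + 1792e-5 * I + 0.49239
  out <- numeric(length(tmean))
  for (k in seq_along(tmean)) {
    Tk <- tmean[k]; m <- month[k]
    if (Tk <= 0) { out[k] <- 0; next }
    delta <- 0.4093 * sin(2 * pi * jday[m] / 365 - 1.405)
    h0 <- acos(max(-1, min(1, -tan(latitude * pi / 180) * tan(delta))))
    L <- 24 * h0 / pi
    K <- (L / 12) * (dm[m] / 30)
    out[k] <- if (Tk >= 26.5) {
      K * (-415.85 + 32.24 * Tk - 0.43 * Tk^2)
    } else {
      16 * K * (10 * Tk / I)^a
    }
  }
  out
}

# drought-event grouping by transitive closure over pairwise year gaps,
# independent of the run-scanning implementation
brute_event_groups <- function(drought_years, separation = 3) {
  if (!length(drought_years)) return(list())
  y <- sort(drought_years)
  n <- length(y)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(y[i] - y[j]) <= separation && grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(y, grp), identity))
}

# LMG by explicit enumeration of all group-order permutations
brute_lmg <- function(y, X, groups) {
  G <- length(groups)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  acc <- setNames(numeric(G), names(groups))
  pp <- perms(seq_len(G))
  for (p in pp) {
    sofar <- character(0)
    for (g in p) {
      cols <- c(sofar, groups[[g]])
      acc[g] <- acc[g] + r2(cols) - r2(sofar)
      sofar <- cols
    }
  }
  acc / length(pp)
}

# small stationary synthetic climate frame for climate-module tests
make_climate <- function(n_years, seed = 1, lat = 42) {
  set.seed(seed)
  mon <- rep(1:12, n_years)
  yrs <- rep(seq_len(n_years) + 1900, each = 12)
  clim <- data.frame(
    year = yrs, month = mon,
    tmean_c = 7 + 15 * cos(2 * pi * (mon - 7) / 12) + rnorm(12 * n_years, 0, 0.7),
    prcp_mm = rgamma(12 * n_years, 4,
                     scale = c(3, 4, 8, 15, 30, 55, 110, 100, 45, 20, 8, 4)[mon] / 4),
    rh_pct = pmin(100, pmax(5, 60 + rnorm(12 * n_years, 0, 5)))
  )
  attr(clim, "latitude") <- lat
  clim
}

# random stand on a rectangle with guaranteed distinct positions
make_stand <- function(n, w = 30, h = 30, seed = 1) {
  set.seed(seed)
  s <- data.frame(tree_id = sprintf("T%03d", seq_len(n)),
                  x_m = runif(n, 0, w), y_m = runif(n, 0, h),
                  dbh_cm = runif(n, 5, 40))
  attr(s, "plot_width") <- w
  attr(s, "plot_height") <- h
  s
}
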