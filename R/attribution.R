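#' Non-overlapping block averages
#'
#' Averages a series over consecutive non-overlapping blocks (default 5
#' years); a trailing partial block is kept only when it holds at least
#' `min_keep` values.
#'
#' @param x Numeric series.
#' @param width Block width (default 5).
#' @param min_keep Minimum length of a kept trailing block (default 3).
#' @return Numeric vector of block means.
#' @examples
#' block_average(1:10)  # 3, 8
#' @export
block_average <- function(x, width = 5, min_keep = 3) {
  n <- length(x)
  if (n < 2 * width) stop("series shorter than two blocks", call. = FALSE)
  grp <- (seq_len(n) - 1) %/% width
  sizes <- tabulate(grp + 1)
  means <- tapply(x, grp, function(v) {
    if (all(is.na(v))) stop("all-missing block", call. = FALSE)
    mean(v, na.rm = TRUE)
  })
  keep <- sizes == width | sizes >= min_keep
  as.numeric(means[keep])
}

#' Fit the block-level growth model
#'
#' Ordinary least squares of log BAI on the selected climate factors, the
#' modelled competition index and the site index, on block-averaged data.
#' Age is deliberately not a predictor. The design condition number is
#' reported and exact collinearity raises an error naming the aliased
#' columns.
#'
#' @param data Data frame of block-level observations.
#' @param response Name of the log-BAI column (default `"log_bai"`).
#' @param climate_vars Character vector of climate predictor columns.
#' @param ci_var Competition index column (default `"ci"`).
#' @param site_var Site index column (default `"site_index"`).
#' @return List of class `growth_model`: `fit` (the `lm`), `r2`, `kappa`,
#'   `groups` (named list of predictor columns per group).
#' @export
fit_growth_model <- function(data, response = "log_bai", climate_vars,
                             ci_var = "ci", site_var = "site_index") {
  preds <- c(climate_vars, ci_var, site_var)
  missing <- setdiff(c(response, preds), names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) <= length(preds) + 2) {
    stop("too few blocks for the number of predictors", call. = FALSE)
  }
  fml <- stats::reformulate(preds, response = response)
  fit <- stats::lm(fml, data = data)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  out <- list(fit = fit, r2 = summary(fit)$r.squared,
              kappa = kappa(scale(X), exact = TRUE),
              groups = list(climate = climate_vars, competition = ci_var,
                            site = site_var),
              data = data, response = response)
  class(out) <- "growth_model"
  out
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("Block-level growth model: R^2 = %.3f, condition number = %.1f\n",
              x$r2, x$kappa))
  print(stats::coef(x$fit))
  invisible(x)
}

# R^2 of an OLS fit of y on the given predictor columns (empty set -> 0)
subset_r2 <- function(y, X, cols) {
  if (!length(cols)) return(0)
  f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative importance of predictor groups
#'
#' Decomposes the model R^2 over predictor groups by the LMG metric: a
#' group's importance is its incremental R^2 when entering the model,
#' averaged over all orderings of the groups. Group importances sum exactly
#' to the full-model R^2. Up to 10 groups are enumerated exactly; more
#' groups would require sampling orderings and are rejected.
#'
#' @param model A [fit_growth_model()] result, or `NULL` when `y`, `X`,
#'   `groups` are given directly.
#' @param y Response vector (when `model` is `NULL`).
#' @param X Numeric predictor matrix with named columns.
#' @param groups Named list mapping group names to column names of `X`.
#' @return Object of class `attribution`: data frame `group`, `lmg`
#'   (absolute R^2 share), `share_pct` (percent of the explained variance),
#'   `share_total_pct` (percent of total variance), plus `r2_total` and
#'   `n` attributes.
#' @export
lmg_importance <- function(model = NULL, y = NULL, X = NULL, groups = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "growth_model"))
    y <- model$data[[model$response]]
    X <- as.matrix(model$data[, unlist(model$groups), drop = FALSE])
    groups <- model$groups
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  G <- length(groups)
  if (G > 10) stop("more than 10 groups: exact enumeration refused", call. = FALSE)
  gnames <- names(groups)

  # R^2 of every subset of groups, keyed by bitmask
  r2 <- numeric(2^G)
  for (mask in 0:(2^G - 1)) {
    cols <- unlist(groups[bitwAnd(mask, 2^(seq_len(G) - 1)) > 0])
    r2[mask + 1] <- subset_r2(y, X, cols)
  }

  lmg <- numeric(G)
  for (g in seq_len(G)) {
    bit <- 2^(g - 1)
    acc <- 0
    for (mask in 0:(2^G - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
      w <- factorial(s) * factorial(G - s - 1) / factorial(G)
      acc <- acc + w * (r2[mask + bit + 1] - r2[mask + 1])
    }
    lmg[g] <- acc
  }
  r2_total <- r2[2^G]
  out <- data.frame(group = gnames, lmg = lmg,
                    share_pct = 100 * lmg / r2_total,
                    share_total_pct = 100 * lmg)
  attr(out, "r2_total") <- r2_total
  attr(out, "n") <- length(y)
  class(out) <- c("attribution", "data.frame")
  out
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("LMG decomposition (total R^2 = %.3f, n = %d)\n",
              attr(x, "r2_total"), attr(x, "n")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Attribute block-level growth to climate, competition and site
#'
#' Convenience wrapper: block-averages log BAI, the climate factor(s) and
#' the modelled CI per stand, fits the growth model across stands and
#' decomposes its R^2 into climate, competition and site shares.
#'
#' @param stands List of per-stand data frames, each with yearly columns
#'   `log_bai`, `ci`, the climate factor columns, and a scalar `site_index`.
#' @param climate_vars Names of the climate factor columns.
#' @param width Block width in years (default 5).
#' @return [lmg_importance()] result, with the fitted model attached as
#'   `attr(, "model")`.
#' @export
attribute_growth <- function(stands, climate_vars, width = 5) {
  blocks <- lapply(stands, function(s) {
    cols <- c("log_bai", "ci", climate_vars)
    b <- lapply(cols, function(cc) block_average(s[[cc]], width = width))
    b <- as.data.frame(stats::setNames(b, cols))
    b$site_index <- s$site_index[1]
    b
  })
  dat <- do.call(rbind, blocks)
  model <- fit_growth_model(dat, response = "log_bai",
                            climate_vars = climate_vars)
  res <- lmg_importance(model)
  attr(res, "model") <- model
  res
}
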