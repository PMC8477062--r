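#' Hegyi distance-dependent competition index
#'
#' For each subject tree `i`, `CI_i = sum_j (D_j / D_i) / d_ij` over all
#' neighbours `j` within `radius` metres, with `D` the DBH (cm) and `d_ij`
#' the stem distance (m). Trees whose neighbourhood disc leaves the plot are
#' flagged `edge`; with `edge_correct = TRUE` the index is divided by the
#' fraction of the disc lying inside the plot (linear-expansion correction).
#'
#' @param stand Data frame with columns `tree_id`, `x_m`, `y_m`, `dbh_cm`;
#'   plot dimensions are read from `attr(stand, "plot_width")` /
#'   `attr(stand, "plot_height")` (metres) when edge information is wanted.
#' @param radius Neighbourhood radius, m (default 8).
#' @param edge_correct Apply the linear-expansion edge correction.
#' @return Data frame `tree_id`, `ci`, `n_competitors`, `class`, `edge`.
#' @examples
#' s <- data.frame(tree_id = 1:2, x_m = c(0, 1), y_m = 0, dbh_cm = c(20, 20))
#' hegyi_ci(s)$ci  # both 1: equal DBH at 1 m
#' @export
hegyi_ci <- function(stand, radius = 8, edge_correct = FALSE) {
  check_stand_frame(stand)
  n <- nrow(stand)
  d <- as.matrix(stats::dist(stand[, c("x_m", "y_m")]))
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("coincident tree positions in stand", call. = FALSE)

  within <- d <= radius
  diag(within) <- FALSE
  ratio <- outer(stand$dbh_cm, stand$dbh_cm, function(di, dj) dj / di)
  contrib <- ifelse(within, ratio / d, 0)
  diag(contrib) <- 0
  ci <- rowSums(contrib)
  ncomp <- rowSums(within)

  pw <- attr(stand, "plot_width")
  ph <- attr(stand, "plot_height")
  edge <- rep(NA, n)
  if (!is.null(pw) && !is.null(ph)) {
    edge <- stand$x_m < radius | stand$x_m > pw - radius |
      stand$y_m < radius | stand$y_m > ph - radius
    if (edge_correct) {
      frac <- vapply(seq_len(n), function(i) {
        circle_rect_fraction(stand$x_m[i], stand$y_m[i], radius, pw, ph)
      }, numeric(1))
      ci <- ci / frac
    }
  } else if (edge_correct) {
    stop("edge correction needs plot dimensions in attributes", call. = FALSE)
  }

  data.frame(tree_id = stand$tree_id, ci = ci, n_competitors = ncomp,
             class = classify_ci(ci), edge = edge)
}

#' Classify competition intensity
#'
#' Stand-level classes: low (`CI < 1`), medium (`1 <= CI < 3`),
#' high (`CI >= 3`).
#'
#' @param ci Numeric competition index, non-negative.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_ci <- function(ci) {
  if (any(ci < 0, na.rm = TRUE)) stop("competition index must be >= 0", call. = FALSE)
  cut(ci, breaks = c(-Inf, 1, 3, Inf), labels = c("low", "medium", "high"),
      right = FALSE)
}

# fraction of a disc of radius r centred at (cx, cy) inside [0,w] x [0,h];
# numerical slice integration, adequate for the linear-expansion correction
circle_rect_fraction <- function(cx, cy, r, w, h, n_slices = 2000) {
  x <- seq(cx - r, cx + r, length.out = n_slices)
  half <- sqrt(pmax(0, r^2 - (x - cx)^2))
  top <- pmin(cy + half, h)
  bot <- pmax(cy - half, 0)
  inside <- ifelse(x >= 0 & x <= w, pmax(0, top - bot), 0)
  area <- sum(inside) * (x[2] - x[1])
  max(min(area / (pi * r^2), 1), 1e-6)
}

#' Growth-rate series of a core
#'
#' Transforms an increment series into annual growth rates,
#' `GR_k = RI_k / RI_total`, which sum to 1 over the series.
#'
#' @param widths Positive annual increments (any consistent unit).
#' @return Numeric vector of the same length summing to 1.
#' @export
growth_rate_series <- function(widths) {
  if (any(widths < 0)) stop("increments must be non-negative", call. = FALSE)
  total <- sum(widths)
  if (total <= 0) stop("zero total increment", call. = FALSE)
  widths / total
}

#' Mean plot growth rate
#'
#' Averages the growth-rate series of the cored trees of a plot year by year
#' over their common span and renormalizes so the plot-level rates sum to 1.
#'
#' @param gr_list Named list of data frames `year`, `gr` (one per cored tree),
#'   or a single long data frame with `tree_id`, `year`, `gr`.
#' @param min_trees Minimum number of cored trees (default 3).
#' @return Data frame `year`, `gr` (plot level).
#' @export
plot_growth_rate <- function(gr_list, min_trees = 3) {
  if (is.data.frame(gr_list)) gr_list <- split(gr_list[c("year", "gr")], gr_list$tree_id)
  if (length(gr_list) < min_trees) {
    stop("need at least ", min_trees, " cored trees", call. = FALSE)
  }
  span <- Reduce(intersect, lapply(gr_list, function(d) d$year))
  if (!length(span)) stop("cored trees share no common year span", call. = FALSE)
  span <- sort(span)
  m <- vapply(gr_list, function(d) d$gr[match(span, d$year)], numeric(length(span)))
  gr <- rowMeans(m)
  data.frame(year = span, gr = gr / sum(gr))
}

#' Back-cast an annual DBH series
#'
#' Cored trees: the diameter at the end of year `k` is the observed DBH minus
#' twice the radial increment laid down after year `k`
#' (`D_k = D_obs - 2 * sum_(j>k) width_j / 10`, mm to cm). Non-cored trees:
#' the rate of diameter growth is assumed equal to the plot-mean radial
#' growth rate, so `D_k = D_obs * sum_(j<=k) gr_j`. Both paths close exactly
#' on the observed DBH in the final year. Years in which the reconstructed
#' diameter falls below `min_dbh` are flagged `below_min` (DBH is undefined
#' before the stem reaches breast height).
#'
#' @param dbh_obs Observed (final inventory) DBH, cm.
#' @param years Calendar years of the reconstruction (ascending).
#' @param widths For a cored tree, the tree-level radial widths (mm) aligned
#'   with `years`; `NULL` for a non-cored tree.
#' @param gr For a non-cored tree, a data frame `year`, `gr` (plot growth
#'   rate) covering `years`; ignored when `widths` is given.
#' @param min_dbh Minimum meaningful DBH, cm (default 1).
#' @return Data frame `year`, `dbh_cm`, `below_min`.
#' @export
backcast_dbh <- function(dbh_obs, years, widths = NULL, gr = NULL, min_dbh = 1) {
  if (dbh_obs <= 0) stop("observed DBH must be positive", call. = FALSE)
  if (!is.null(widths)) {
    if (length(widths) != length(years)) stop("widths/years length mismatch", call. = FALSE)
    later <- rev(cumsum(rev(widths))) - widths  # sum of widths after year k
    dbh <- dbh_obs - 2 * later / 10
  } else {
    if (is.null(gr)) stop("need either `widths` or `gr`", call. = FALSE)
    g <- gr$gr[match(years, gr$year)]
    if (anyNA(g)) stop("growth-rate series does not cover all years", call. = FALSE)
    dbh <- dbh_obs * cumsum(g) / sum(g)
  }
  below <- dbh < min_dbh
  data.frame(year = years, dbh_cm = pmax(dbh, 0), below_min = below)
}

#' Reconstruct annual competition indices for the cored trees of a plot
#'
#' Rebuilds every tree's annual DBH (cored trees by subtracting their own
#' radial increments, non-cored trees by the plot growth-rate path), then
#' evaluates the Hegyi index year by year with the year-specific diameters.
#' The final-year index equals the index computed from the observed
#' inventory. Years in which the subject or any competitor within the radius
#' is below `min_dbh` are reported as `NA`.
#'
#' @param stand Stand inventory data frame (`tree_id`, `x_m`, `y_m`,
#'   `dbh_cm`, `cored`), plot dimensions in attributes.
#' @param rings Long ring-width data frame for the cored trees (`core_id`,
#'   `tree_id`, `year`, `width_mm`).
#' @param radius Neighbourhood radius, m.
#' @param min_dbh Minimum meaningful DBH, cm.
#' @param include_cored_competitors Whether cored neighbours enter the
#'   competitor set with their own back-cast histories (default `TRUE`).
#' @return Long data frame `tree_id`, `year`, `ci`.
#' @export
reconstruct_ci <- function(stand, rings, radius = 8, min_dbh = 1,
                           include_cored_competitors = TRUE) {
  check_stand_frame(stand)
  check_rings_frame(rings)
  if (!"cored" %in% names(stand)) stop("stand needs a `cored` column", call. = FALSE)

  cored_ids <- intersect(stand$tree_id[stand$cored == 1], unique(rings$tree_id))
  if (length(cored_ids) < 3) stop("need at least 3 cored trees with rings", call. = FALSE)

  # tree-level widths (mean of cores) and growth rates
  tree_w <- lapply(cored_ids, function(id) {
    tr <- rings[rings$tree_id == id, , drop = FALSE]
    w <- tapply(tr$width_mm, tr$year, mean)
    data.frame(year = as.integer(names(w)), width_mm = as.numeric(w))
  })
  names(tree_w) <- cored_ids
  gr_list <- lapply(tree_w, function(d) data.frame(year = d$year,
                                                   gr = growth_rate_series(d$width_mm)))
  plot_gr <- plot_growth_rate(gr_list)
  years <- plot_gr$year

  # reconstruct every tree's DBH over the common span
  dbh_mat <- matrix(NA_real_, length(years), nrow(stand),
                    dimnames = list(years, stand$tree_id))
  below <- matrix(FALSE, length(years), nrow(stand))
  for (i in seq_len(nrow(stand))) {
    id <- as.character(stand$tree_id[i])
    if (id %in% names(tree_w)) {
      d <- tree_w[[id]]
      w <- d$width_mm[match(years, d$year)]
      if (anyNA(w)) {
        bc <- backcast_dbh(stand$dbh_cm[i], years, gr = plot_gr, min_dbh = min_dbh)
      } else {
        bc <- backcast_dbh(stand$dbh_cm[i], years, widths = w, min_dbh = min_dbh)
      }
    } else {
      bc <- backcast_dbh(stand$dbh_cm[i], years, gr = plot_gr, min_dbh = min_dbh)
    }
    dbh_mat[, i] <- bc$dbh_cm
    below[, i] <- bc$below_min
  }

  dmat <- as.matrix(stats::dist(stand[, c("x_m", "y_m")]))
  if (any(dmat[upper.tri(dmat)] == 0)) {
    stop("coincident tree positions in stand", call. = FALSE)
  }
  is_cored <- stand$tree_id %in% cored_ids

  out <- list()
  for (id in cored_ids) {
    i <- which(stand$tree_id == id)
    nb <- which(dmat[i, ] <= radius & seq_len(nrow(stand)) != i)
    if (!include_cored_competitors) nb <- nb[!is_cored[nb]]
    ci <- vapply(seq_along(years), function(k) {
      if (below[k, i] || any(below[k, nb])) return(NA_real_)
      if (!length(nb)) return(0)
      sum((dbh_mat[k, nb] / dbh_mat[k, i]) / dmat[i, nb])
    }, numeric(1))
    out[[length(out) + 1]] <- data.frame(tree_id = id, year = years, ci = ci)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_stand_frame <- function(stand) {
  need <- c("tree_id", "x_m", "y_m", "dbh_cm")
  missing <- setdiff(need, names(stand))
  if (length(missing)) {
    stop("stand table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(stand$tree_id)) stop("duplicate tree ids", call. = FALSE)
  if (any(stand$dbh_cm <= 0)) stop("DBH must be positive", call. = FALSE)
  pw <- attr(stand, "plot_width"); ph <- attr(stand, "plot_height")
  if (!is.null(pw) && !is.null(ph)) {
    if (any(stand$x_m < 0 | stand$x_m > pw | stand$y_m < 0 | stand$y_m > ph)) {
      stop("tree positions outside the plot rectangle", call. = FALSE)
    }
  }
  invisible(TRUE)
}
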