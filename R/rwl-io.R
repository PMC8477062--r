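#' Read a Tucson (decadal) ring-width file
#'
#' Parses the classical `.rwl` exchange format: one physical line per series
#' and decade, series id followed by the first year of the line and up to ten
#' width values in units of 0.01 mm, with `999` terminating a series (the
#' `-9999` terminator, units 0.001 mm, is also recognised).
#'
#' @param path File path.
#' @return Long data frame `core_id`, `year`, `width_mm`.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 3) next
    id <- toks[1]
    year0 <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(year0) || anyNA(vals)) {
      stop("malformed .rwl line: ", ln, call. = FALSE)
    }
    scale <- 100
    term <- which(vals == 999 | vals == -9999)
    if (length(term)) {
      if (vals[term[1]] == -9999) scale <- 1000
      vals <- vals[seq_len(term[1] - 1)]
    }
    if (!length(vals)) next
    out[[length(out) + 1]] <- data.frame(
      core_id = id,
      year = seq(year0, length.out = length(vals)),
      width_mm = vals / scale
    )
  }
  if (!length(out)) stop("no ring-width series found in ", path, call. = FALSE)
  res <- do.call(rbind, out)
  # a series may span several physical lines; keep ordered and unique
  res <- res[order(res$core_id, res$year), , drop = FALSE]
  if (anyDuplicated(res[c("core_id", "year")])) {
    stop("duplicate (core, year) records in ", path, call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write a Tucson (decadal) ring-width file
#'
#' @param rings Long data frame `core_id`, `year`, `width_mm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rings, path) {
  stopifnot(all(c("core_id", "year", "width_mm") %in% names(rings)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(as.character(rings$core_id))) {
    s <- rings[rings$core_id == id, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    if (any(diff(s$year) != 1)) {
      stop("core ", id, " has non-contiguous years", call. = FALSE)
    }
    vals <- round(s$width_mm * 100)
    yrs <- s$year
    i <- 1
    n <- length(vals)
    while (i <= n) {
      y <- yrs[i]
      decade_end <- (y %/% 10) * 10 + 9
      j <- min(n, i + (decade_end - y))
      row_vals <- vals[i:j]
      if (j == n) row_vals <- c(row_vals, 999)
      writeLines(sprintf("%-8s%4d%s", substr(id, 1, 8), y,
                         paste(sprintf("%6d", row_vals), collapse = "")), con)
      i <- j + 1
    }
  }
  invisible(path)
}
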