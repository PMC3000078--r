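# Reading, writing and pre-processing of scan curves and probe traces.
#
# File format: plain CSV, "#"-prefixed comment lines carry metadata
# (key: value), columns are (abscissa, ordinate[, ordinate2]).  There is no
# community standard for DSC exports, so the dialect is deliberately simple
# and fully declared in the header.

#' Read a curve file
#'
#' Reads a two- or three-column CSV curve (comment lines start with `#`)
#' and returns a validated [thermogram()] or [probe_trace()].  Temperatures
#' given in degrees Celsius are converted to kelvin (T\[K\] = T\[degC\] +
#' 273.15); rows are sorted by abscissa and duplicated abscissa values are
#' rejected.  Header comments of the form `# key: value` override dialect
#' entries (recognised keys: `kind`, `temperature_unit`, `heating_rate`,
#' `T_ann`, `t_ann`, `incubation_K`, `label`).
#'
#' @param path Path to the CSV file.
#' @param dialect Named list: `kind` (`"thermogram"`, `"dls"`, `"activity"`,
#'   `"fluorescence"`), `temperature_unit` (`"K"` or `"C"`), `heating_rate`,
#'   optional `T_ann`/`t_ann`, `incubation_K`.
#' @return A `thermogram` or `probe_trace` object.
#' @export
read_curve <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_header_meta(lines[is_comment])
  dialect <- modifyList(default_dialect(), dialect)
  dialect <- modifyList(dialect, meta)

  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) == 0) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[data_idx]), ",")
  ncol <- length(rows[[1]])
  if (!ncol %in% c(2L, 3L))
    stop("expected 2 or 3 numeric columns, found ", ncol, " at line ",
         data_idx[1])
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    r <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(r) != ncol || anyNA(r))
      stop("malformed row at line ", data_idx[i], " of ", path, ": '",
           lines[data_idx[i]], "'")
    vals[i, ] <- r
  }

  ord <- order(vals[, 1])
  vals <- vals[ord, , drop = FALSE]
  if (anyDuplicated(vals[, 1]))
    stop("duplicated abscissa values in ", path)

  kind <- dialect$kind
  if (kind == "thermogram") {
    tk <- convert_temperature(vals[, 1], dialect$temperature_unit)
    ann <- NULL
    if (!is.null(dialect$T_ann) && !is.null(dialect$t_ann))
      ann <- c(T_ann = as.numeric(dialect$T_ann),
               t_ann = as.numeric(dialect$t_ann))
    thermogram(tk, vals[, 2],
               heating_rate = as.numeric(dialect$heating_rate),
               annealing = ann,
               label = dialect$label %||% "")
  } else {
    absc <- vals[, 1]
    if (kind == "fluorescence")
      absc <- convert_temperature(absc, dialect$temperature_unit)
    probe_trace(absc, vals[, 2],
                ordinate2 = if (ncol == 3) vals[, 3] else NULL,
                kind = kind,
                temperature = as.numeric(dialect$incubation_K %||% NA_real_),
                label = dialect$label %||% "")
  }
}

#' Write a curve file
#'
#' Writes a [thermogram()] or [probe_trace()] as CSV with a `#`-comment
#' header declaring units and metadata, so that [read_curve()] reproduces
#' the object (abscissa values are written in kelvin for thermograms).
#'
#' @param x A `thermogram` or `probe_trace`.
#' @param path Output path.
#' @param digits Significant digits written (default 17: round-trip exact).
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path, digits = 17) {
  hdr <- character()
  if (inherits(x, "thermogram")) {
    hdr <- c("# kind: thermogram", "# temperature_unit: K",
             sprintf("# heating_rate: %.10g", x$heating_rate))
    if (!is.null(x$annealing))
      hdr <- c(hdr, sprintf("# T_ann: %.10g", x$annealing[["T_ann"]]),
               sprintf("# t_ann: %.10g", x$annealing[["t_ann"]]))
    if (nzchar(x$label)) hdr <- c(hdr, paste0("# label: ", x$label))
    body <- paste(formatC(x$temperature, digits = digits, format = "g"),
                  formatC(x$heat_capacity, digits = digits, format = "g"),
                  sep = ",")
  } else if (inherits(x, "probe_trace")) {
    hdr <- c(paste0("# kind: ", x$kind),
             if (x$kind == "fluorescence") "# temperature_unit: K",
             if (is.finite(x$temperature))
               sprintf("# incubation_K: %.10g", x$temperature))
    if (nzchar(x$label)) hdr <- c(hdr, paste0("# label: ", x$label))
    cols <- list(x$abscissa, x$ordinate)
    if (!is.null(x$ordinate2)) cols <- c(cols, list(x$ordinate2))
    body <- do.call(paste, c(lapply(cols, formatC, digits = digits,
                                    format = "g"),
                             list(sep = ",")))
  } else stop("unsupported object")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Inverted-cell instrumental background subtraction
#'
#' Removes the instrumental baseline using a second scan recorded with the
#' sample and reference cells swapped, which inverts the protein signal but
#' not the cell mismatch.  In the default `"half-difference"` mode the
#' result is `(sample - inverted) / 2`; mode `"difference"` returns the
#' plain difference.  If the grids differ, the inverted curve is linearly
#' interpolated onto the sample grid (ranges must overlap fully).
#'
#' @param sample Thermogram from the normal cell arrangement.
#' @param inverted Thermogram from the swapped arrangement.
#' @param mode `"half-difference"` (default) or `"difference"`.
#' @return A `thermogram` on the sample grid; the mode used is recorded in
#'   the label.
#' @export
subtract_background <- function(sample, inverted,
                                mode = c("half-difference", "difference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "thermogram"), inherits(inverted, "thermogram"))
  tg <- sample$temperature
  if (min(inverted$temperature) > min(tg) + 1e-9 ||
      max(inverted$temperature) < max(tg) - 1e-9)
    stop("inverted curve does not cover the sample temperature range")
  inv <- approx(inverted$temperature, inverted$heat_capacity, xout = tg)$y
  d <- sample$heat_capacity - inv
  if (mode == "half-difference") d <- d / 2
  thermogram(tg, d, heating_rate = sample$heating_rate,
             annealing = sample$annealing,
             label = paste0(sample$label,
                            sprintf(" [background-subtracted: %s]", mode)))
}

#' Excess heat capacity from a thermogram and a baseline
#'
#' Subtracts a (chemical) baseline from a thermogram on an analysis window
#' and integrates: \eqn{C_p^{ex} = C_p - baseline},
#' \eqn{Q^{ex}(T) = \int_{T_1}^{T} C_p^{ex} dT} by trapezoid on the native
#' grid, \eqn{\Delta H_{trans} = Q^{ex}} at the window end.
#'
#' @param curve A `thermogram`.
#' @param baseline Numeric vector on `curve`'s grid, a single number, a
#'   function of temperature, or a [fit_baseline()] result.
#' @param window Optional `c(Tmin, Tmax)` analysis window in K (must lie
#'   inside the grid); default: the full grid (or the anchor window of a
#'   baseline fit).
#' @return An [excess_curve()].
#' @export
compute_excess <- function(curve, baseline = 0, window = NULL) {
  stopifnot(inherits(curve, "thermogram"))
  tg <- curve$temperature
  if (inherits(baseline, "baseline_fit")) {
    if (is.null(window)) window <- range(baseline$anchors)
    baseline <- approx(baseline$temperature, baseline$baseline, xout = tg,
                       rule = 2)$y
  }
  if (is.function(baseline)) baseline <- baseline(tg)
  if (length(baseline) == 1) baseline <- rep(baseline, length(tg))
  if (length(baseline) != length(tg))
    stop("baseline must match the thermogram grid")
  if (is.null(window)) window <- range(tg)
  if (window[1] < min(tg) - 1e-9 || window[2] > max(tg) + 1e-9)
    stop("analysis window outside the temperature grid")
  keep <- tg >= window[1] - 1e-12 & tg <= window[2] + 1e-12
  excess_curve(tg[keep], curve$heat_capacity[keep] - baseline[keep],
               heating_rate = curve$heating_rate)
}

convert_temperature <- function(x, unit) {
  switch(toupper(substr(unit, 1, 1)),
         K = x,
         C = x + 273.15,
         stop("temperature unit must be 'K' or 'C'"))
}

default_dialect <- function() {
  list(kind = "thermogram", temperature_unit = "K", heating_rate = 1,
       label = "")
}

parse_header_meta <- function(comment_lines) {
  meta <- list()
  for (ln in comment_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (k in c("heating_rate", "T_ann", "t_ann", "incubation_K"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
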