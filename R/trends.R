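# Anomaly trend detection on sweep tables: sign patterns of finite
# differences on the table's own grid spacing (no interpolation).

#' Shape of a numeric series
#'
#' Classifies a series by the run-length-compressed sign pattern of its
#' successive differences: `"flat"`, `"increasing"`, `"decreasing"`,
#' `"interior_max"` (rises then falls), `"interior_min"` (falls then rises)
#' or `"mixed"`. Differences smaller than `tol` times the series scale count
#' as zero, so a numerically flat table reports no extrema.
#'
#' @param y Numeric vector (length >= 3 for extremum detection).
#' @param tol Relative tolerance below which a difference counts as zero.
#' @return A single character string.
#' @examples
#' series_shape(c(1, 2, 3))        # "increasing"
#' series_shape(c(1, 3, 2))        # "interior_max"
#' series_shape(rep(1, 5))         # "flat"
#' @export
series_shape <- function(y, tol = 1e-12) {
  if (length(y) < 2) stop("need at least 2 points", call. = FALSE)
  d <- diff(y)
  scale <- max(abs(y), 1e-300)
  s <- sign(d)
  s[abs(d) < tol * scale] <- 0
  s <- s[s != 0]
  if (length(s) == 0) return("flat")
  runs <- rle(s)$values
  if (identical(runs, c(1))) return("increasing")
  if (identical(runs, c(-1))) return("decreasing")
  if (identical(runs, c(1, -1))) return("interior_max")
  if (identical(runs, c(-1, 1))) return("interior_min")
  "mixed"
}

#' Anomaly trend report for a sweep table
#'
#' Summarizes, from a [run_sweep()] table, the qualitative behaviour the
#' model is known for:
#' per isobar, the shape of `D(T)`, `eta(T)` and `kappa_th(T)` (detecting
#' the interior conductivity maximum of the high-pressure regime); per
#' isotherm, the sign pattern of `dD/dp` (detecting the low-temperature
#' diffusion maximum, where compression first frees molecules from cages
#' and only then slows them).
#'
#' @param tab A data frame from [run_sweep()], covering at least 3
#'   temperatures per isobar and/or 3 pressures per isotherm.
#' @return A list of class `trend_report` with data frames `isobars`
#'   (`p_star`, `d_shape`, `eta_shape`, `kappa_shape`) and `isotherms`
#'   (`t_star`, `d_shape`, `d_interior_max`, `dDdp_positive_somewhere`).
#' @examples
#' tab <- run_sweep(t_grid = seq(0.15, 0.35, length.out = 9),
#'                  p_values = c(0.05, 0.19))
#' trend_report(tab)
#' @export
trend_report <- function(tab) {
  need <- c("t_star", "p_star", "d_total", "eta", "kappa_th")
  if (!all(need %in% names(tab)))
    stop("'tab' must be a run_sweep() table with columns ",
         paste(need, collapse = ", "), call. = FALSE)

  isobars <- NULL
  for (p in unique(tab$p_star)) {
    sub <- tab[tab$p_star == p, ]
    sub <- sub[order(sub$t_star), ]
    if (nrow(sub) < 3) next
    isobars <- rbind(isobars, data.frame(
      p_star = p,
      d_shape = series_shape(sub$d_total),
      eta_shape = series_shape(sub$eta),
      kappa_shape = series_shape(sub$kappa_th)
    ))
  }
  isotherms <- NULL
  for (t in unique(tab$t_star)) {
    sub <- tab[tab$t_star == t, ]
    sub <- sub[order(sub$p_star), ]
    if (nrow(sub) < 3) next
    shp <- series_shape(sub$d_total)
    isotherms <- rbind(isotherms, data.frame(
      t_star = t,
      d_shape = shp,
      d_interior_max = shp == "interior_max",
      dDdp_positive_somewhere = any(diff(sub$d_total) > 0)
    ))
  }
  if (is.null(isobars) && is.null(isotherms))
    stop("insufficient grid: need at least 3 temperatures per isobar or 3 pressures per isotherm",
         call. = FALSE)
  structure(list(isobars = isobars, isotherms = isotherms),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("trend report\n")
  if (!is.null(x$isobars)) {
    cat("isobars (vs T*):\n")
    print(x$isobars, row.names = FALSE)
  }
  if (!is.null(x$isotherms)) {
    cat("isotherms (vs p*):\n")
    print(x$isotherms, row.names = FALSE)
  }
  invisible(x)
}
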