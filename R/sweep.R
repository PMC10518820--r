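# Grid sweeps over (T*, p*) and CSV emission.

#' Default (T*, p*) property grid
#'
#' The standard evaluation window of the model: 50 reduced temperatures in
#' `[0.12, 0.40]` by 20 reduced pressures in `[1e-4, 1]` (1000 state points
#' spanning the supercooled-to-hot liquid range).
#'
#' @return A list with numeric vectors `t` and `p`.
#' @export
default_grid <- function() {
  list(t = seq(0.12, 0.40, length.out = 50),
       p = seq(1e-4, 1.0, length.out = 20))
}

#' Specification of a property sweep
#'
#' @param t_min,t_max Reduced-temperature range (`t_min < t_max`).
#' @param t_steps Number of temperatures (>= 2).
#' @param p_values Reduced pressures of the isobars (all >= 0).
#' @param out_path Optional CSV output path.
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec(0.15, 0.35, 21, c(0.05, 0.19))
#' @export
sweep_spec <- function(t_min, t_max, t_steps, p_values, out_path = NULL) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(t_steps),
            is.numeric(p_values))
  if (!(t_min < t_max)) stop("'t_min' must be < 't_max'", call. = FALSE)
  if (t_steps < 2) stop("'t_steps' must be >= 2", call. = FALSE)
  if (any(p_values < 0)) stop("all pressures must be >= 0", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max, t_steps = as.integer(t_steps),
                 p_values = as.numeric(p_values), out_path = out_path),
            class = "sweep_spec")
}

#' Run a property sweep over a (T*, p*) grid
#'
#' Evaluates the full equilibrium and transport property set at every grid
#' point and returns one row per `(T*, p*)` pair, temperature-major (the
#' temperature is the outer loop). The pipeline is deterministic: rerunning
#' a sweep reproduces the table exactly.
#'
#' @param spec A [sweep_spec()], or `NULL` to use grids given via `t_grid`
#'   and `p_values`.
#' @param params An [mb_params()] object.
#' @param t_grid,p_values Explicit grids, used when `spec` is `NULL`.
#' @return A data frame with columns `t_star`, `p_star`, the
#'   [equilibrium_properties()] fields (`f_hb`, `f_lj`, `f_0`, `f_c`, `g`,
#'   `v`, `h`, `s`, `rho`, `kappa_t`, `alpha_p`, `cp`, `cv`) and the
#'   transport set (`d_total`, `d_hb`, `d_lj`, `d_0`, `d_c`, `eta`, `d_avg`,
#'   `c_s`, `kappa_th`, `a_th`). If `spec$out_path` is set the table is also
#'   written with [write_sweep_csv()].
#' @examples
#' tab <- run_sweep(sweep_spec(0.2, 0.3, 3, 0.19))
#' tab$d_total
#' @export
run_sweep <- function(spec = NULL, params = mb_params(),
                      t_grid = NULL, p_values = NULL) {
  if (!is.null(spec)) {
    if (!inherits(spec, "sweep_spec")) stop("'spec' must be a sweep_spec",
                                            call. = FALSE)
    t_grid <- seq(spec$t_min, spec$t_max, length.out = spec$t_steps)
    p_values <- spec$p_values
  }
  if (is.null(t_grid) || is.null(p_values))
    stop("provide either 'spec' or both 't_grid' and 'p_values'", call. = FALSE)

  rows <- vector("list", length(t_grid) * length(p_values))
  i <- 0L
  for (t in t_grid) {
    for (p in p_values) {
      st <- thermo_state(t, p)
      eq <- equilibrium_properties(st, params)
      dyn <- dynamic_properties(st, params, eq)
      i <- i + 1L
      rows[[i]] <- data.frame(
        t_star = t, p_star = p,
        f_hb = eq$f_hb, f_lj = eq$f_lj, f_0 = eq$f_0, f_c = eq$f_c,
        g = eq$g, v = eq$v, h = eq$h, s = eq$s, rho = eq$rho,
        kappa_t = eq$kappa_t, alpha_p = eq$alpha_p, cp = eq$cp, cv = eq$cv,
        d_total = dyn$d_total,
        d_hb = dyn$d_by_state[["d_hb"]], d_lj = dyn$d_by_state[["d_lj"]],
        d_0 = dyn$d_by_state[["d_0"]], d_c = dyn$d_by_state[["d_c"]],
        eta = dyn$eta, d_avg = dyn$d_avg, c_s = dyn$c_s,
        kappa_th = dyn$kappa_th, a_th = dyn$a_th
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(spec) && !is.null(spec$out_path))
    write_sweep_csv(tab, spec$out_path)
  tab
}

#' Write a property table as CSV
#'
#' Comma-separated, header row mandatory, `.` decimal separator, UTF-8,
#' values at 10 significant digits. Deterministic: the same table always
#' produces a byte-identical file.
#'
#' @param tab A data frame from [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(tab, path) {
  fmt <- vapply(tab, function(col) {
    if (is.numeric(col)) formatC(col, digits = 10, format = "g") else
      as.character(col)
  }, character(nrow(tab)))
  fmt <- matrix(fmt, nrow = nrow(tab),
                dimnames = list(NULL, names(tab)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(fmt), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a property table written by [write_sweep_csv()]
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
}
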