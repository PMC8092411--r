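#' Metabolite exchange rates from supernatant concentrations
#'
#' Converts a supernatant concentration series and a viable-cell density
#' series into per-interval exchange rates, normalised per cell and per
#' hour: over `[t1, t2]` the rate is
#' `(C(t2) - C(t1)) * V / integral(N(t) dt)`, with the cell integral taken
#' by the trapezoid rule on the measured densities (converted to total
#' cells via the culture volume) and time in hours. Units are nmol per 1e6
#' cells per hour; negative rates are consumption, positive rates release.
#'
#' @param supernatant data.frame with columns `day` and `concentration_mM`
#'   (one metabolite), or a `supernatant_series` from
#'   [simulate_supernatant()] (then `metabolite` selects the series and
#'   `cells`/`volume_ml` default from the object).
#' @param cells data.frame with columns `day` and `cells_per_ml`.
#' @param volume_ml culture volume in mL.
#' @param metabolite metabolite name when `supernatant` holds several.
#' @return data.frame of class `exchange_rate_series`: `t_start`, `t_end`
#'   (days), `rate` (nmol / 1e6 cells / h).
#' @export
#' @examples
#' sup <- data.frame(day = c(0, 1), concentration_mM = c(10, 8))
#' cells <- data.frame(day = c(0, 1), cells_per_ml = c(1e6, 1e6))
#' exchange_rates(sup, cells, volume_ml = 1)  # about -83.3
exchange_rates <- function(supernatant, cells = NULL, volume_ml = NULL,
                           metabolite = NULL) {
  if (inherits(supernatant, "supernatant_series")) {
    obj <- supernatant
    cells <- cells %||% obj$cells
    volume_ml <- volume_ml %||% obj$volume_ml
    supernatant <- obj$supernatant
    if (!is.null(metabolite)) {
      supernatant <- supernatant[supernatant$metabolite == metabolite, ]
    } else if (length(unique(supernatant$metabolite)) > 1) {
      stop("several metabolites present; pick one with `metabolite`")
    }
  }
  if (is.null(volume_ml)) stop("culture volume (volume_ml) is required")
  if (is.null(cells)) stop("viable-cell series is required")
  stopifnot(all(c("day", "concentration_mM") %in% names(supernatant)),
            all(c("day", "cells_per_ml") %in% names(cells)))
  shared <- intersect(supernatant$day, cells$day)
  if (length(shared) < 2) stop("need at least 2 shared timepoints")
  shared <- sort(shared)
  conc <- supernatant$concentration_mM[match(shared, supernatant$day)]
  dens <- cells$cells_per_ml[match(shared, cells$day)]
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (any(dens <= 0)) stop("viable-cell densities must be > 0")

  n <- length(shared)
  rate <- vapply(seq_len(n - 1), function(k) {
    delta_nmol <- (conc[k + 1] - conc[k]) * 1000 * volume_ml  # mM*mL -> nmol
    cell_hours <- trapz(shared[k:(k + 1)] * 24, dens[k:(k + 1)] * volume_ml)
    delta_nmol / (cell_hours / 1e6)
  }, numeric(1))
  structure(data.frame(t_start = shared[-n], t_end = shared[-1], rate = rate),
            class = c("exchange_rate_series", "data.frame"))
}
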