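#' Equilibrium summary of a trajectory
#'
#' Declares a Malthusian steady state at the first year after which the
#' absolute annual growth rate stays below `threshold` (in percent per year)
#' through the end of the run. Also reports the peak of carrying capacity and
#' the most negative realized elasticity after that peak, and flags
#' boom-and-bust regimes (more than one sign change in `dP`).
#'
#' @param traj a `ccpop_trajectory`.
#' @param threshold steady-state threshold on `|pct_growth|`, percent/year
#'   (default `1e-4`).
#' @return `ccpop_equilibrium`: list with `reached`, `year_of_steady_state`,
#'   `P_infinity`, `K_infinity`, `peak_K` (`c(year, K)`),
#'   `min_elasticity_after_peak`, `oscillating` (logical), `n_dP_sign_changes`
#'   and `collapse` (`NULL` or the trajectory's collapse event).
#' @export
summarize_equilibrium <- function(traj, threshold = 1e-4) {
  p <- traj$points
  n <- nrow(p)
  collapse <- traj$collapse
  sign_changes <- sum(diff(sign(p$dP[p$dP != 0])) != 0)
  oscillating <- sign_changes > 1
  below <- abs(p$pct_growth) < threshold
  # first index from which `below` holds through the end of the run
  run_ok <- rev(cumprod(rev(below))) > 0
  idx <- which(run_ok)
  reached <- is.null(collapse) && length(idx) > 0
  structure(
    list(
      reached = reached,
      year_of_steady_state = if (reached) p$year[idx[1]] else NA_integer_,
      P_infinity = p$P[n], K_infinity = p$K[n],
      peak_K = c(year = p$year[which.max(p$K)], K = max(p$K)),
      min_elasticity_after_peak = {
        after <- p$c_realized[p$year >= p$year[which.max(p$K)]]
        if (all(is.na(after))) NA_real_ else min(after, na.rm = TRUE)
      },
      oscillating = oscillating,
      n_dP_sign_changes = sign_changes,
      collapse = collapse,
      threshold = threshold
    ),
    class = "ccpop_equilibrium"
  )
}

#' @export
print.ccpop_equilibrium <- function(x, ...) {
  cat("<ccpop equilibrium summary>\n")
  if (!is.null(x$collapse)) {
    cat(sprintf("  collapsed in %d (%s)\n", x$collapse$year,
                x$collapse$reason))
  } else if (x$reached) {
    cat(sprintf("  steady state from %d (|growth| < %g %%/yr)\n",
                x$year_of_steady_state, x$threshold))
  } else {
    cat(sprintf("  no steady state at threshold %g %%/yr%s\n", x$threshold,
                if (x$oscillating) " (oscillating)" else ""))
  }
  cat(sprintf("  final: P = %.5g, K = %.5g; peak K = %.5g in %d\n",
              x$P_infinity, x$K_infinity, x$peak_K[["K"]],
              as.integer(x$peak_K[["year"]])))
  invisible(x)
}

#' Realized elasticity and growth-rate series
#'
#' Extracts the two series plotted in elasticity diagnostics: the realized
#' population elasticity of carrying capacity \eqn{c_t = \Delta K_t/\Delta
#' P_t} (missing where \eqn{\Delta P_t = 0}) and the percent annual
#' population change.
#'
#' @param traj a `ccpop_trajectory`.
#' @return data.frame `year, c_realized, pct_growth`.
#' @export
elasticity_series <- function(traj) {
  traj$points[, c("year", "c_realized", "pct_growth")]
}

#' Signed percent error of the modelled 2012 population
#'
#' `100 * (P_2012 - 7.00e9) / 7.00e9`. The 7.00e9 reference is the 2012
#' census aggregate and is deliberately fixed, not configurable, so that
#' reported percent errors are comparable across runs.
#'
#' @param traj a `ccpop_trajectory` covering 2012.
#' @return signed percent.
#' @export
pct_error_2012 <- function(traj) {
  p <- trajectory_at(traj, 2012)
  if (is.na(p)) state_error("trajectory does not cover 2012")
  100 * (p - 7.00e9) / 7.00e9
}

#' Is the 2100 CE population within the plausible projection range?
#'
#' Checks `6e9 <= P_2100 <= 17e9` (inclusive), the envelope spanned by
#' published 21st-century demographic projections from imminent decline
#' toward ~6–7 billion up to continued growth to ~17 billion.
#'
#' @param traj a `ccpop_trajectory` covering 2100.
#' @return list with `within` (logical), `margin` (persons to the nearest
#'   bound; >= 0 inside the range, negative outside), and `P_2100`.
#' @export
un_range_check <- function(traj) {
  p <- trajectory_at(traj, 2100)
  if (is.na(p)) state_error("trajectory does not cover 2100")
  lo <- 6e9
  hi <- 17e9
  within <- p >= lo && p <= hi
  margin <- if (within) min(p - lo, hi - p) else -min(abs(p - lo), abs(p - hi))
  list(within = within, margin = margin, P_2100 = p)
}

#' Read an overlay series
#'
#' Import hook for juxtaposing an external annual series (e.g. a climate
#' proxy) on trajectory plots: a CSV with columns `year, value`. No external
#' data is bundled.
#'
#' @param path CSV path.
#' @return data.frame `year, value`.
#' @export
read_overlay <- function(path) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  d <- read.csv(path)
  if (!all(c("year", "value") %in% names(d))) {
    data_error("overlay CSV must have columns year, value")
  }
  d[, c("year", "value")]
}

#' Plot a trajectory
#'
#' Semilog population-versus-year plot with the carrying capacity and an
#' optional observation overlay. Plotting is a convenience; nothing in the
#' package depends on it.
#'
#' @param traj a `ccpop_trajectory`.
#' @param obs optional `ccpop_observations` overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `traj`.
#' @export
plot_trajectory <- function(traj, obs = NULL, ...) {
  p <- traj$points
  graphics::plot(p$year, p$P, type = "l", log = "y", xlab = "year CE",
                 ylab = "persons", col = "black", ...)
  graphics::lines(p$year, p$K, lty = 2, col = "grey40")
  if (!is.null(obs)) {
    graphics::points(obs$aggregate$year, obs$aggregate$value,
                     pch = 8, col = "red")
  }
  graphics::legend("topleft", legend = c("P", "K"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n")
  invisible(traj)
}

#' @rdname plot_trajectory
#' @export
plot_elasticity <- function(traj, ...) {
  s <- elasticity_series(traj)
  old <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(old))
  graphics::plot(s$year, s$c_realized, type = "l", xlab = "year CE",
                 ylab = "realized elasticity c_t", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(s$year, s$pct_growth, type = "l", col = "blue", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("% annual population change", side = 4, line = 2.5,
                  col = "blue")
  invisible(traj)
}

#' Write a run report
#'
#' Writes a plain-text + CSV bundle for one trajectory: the trajectory CSV,
#' a key-value summary (spec, equilibrium, fit if observations given, 2012
#' percent error and 2100 range check when covered), and optional PNG plots.
#' All quantities are pure functions of the trajectory; nothing is
#' re-simulated.
#'
#' @param traj a `ccpop_trajectory`.
#' @param dir output directory (created if needed).
#' @param obs optional `ccpop_observations` for fit lines and plot overlay.
#' @param plots write PNG plots (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(traj, dir, obs = NULL, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_csv(traj, file.path(dir, "trajectory.csv"))
  s <- traj$spec
  eq <- summarize_equilibrium(traj)
  kv <- c(
    sprintf("law=%s", s$law), sprintf("P0=%.10g", s$P0),
    sprintf("K0=%.10g", s$K0), sprintf("r_soc=%.10g", s$r_soc),
    sprintf("L=%.10g", s$L), sprintf("a=%.10g", s$a), sprintf("b=%.10g", s$b),
    sprintf("t0=%d", s$t0), sprintf("t_end=%d", s$t_end),
    sprintf("collapsed=%s", !is.null(traj$collapse)),
    sprintf("steady_state_reached=%s", eq$reached),
    sprintf("year_of_steady_state=%s", eq$year_of_steady_state),
    sprintf("P_infinity=%.10g", eq$P_infinity),
    sprintf("K_infinity=%.10g", eq$K_infinity),
    sprintf("peak_K_year=%d", as.integer(eq$peak_K[["year"]])),
    sprintf("peak_K=%.10g", eq$peak_K[["K"]])
  )
  if (!is.na(trajectory_at(traj, 2012))) {
    kv <- c(kv, sprintf("pct_error_2012=%.6g", pct_error_2012(traj)))
  }
  if (!is.na(trajectory_at(traj, 2100))) {
    un <- un_range_check(traj)
    kv <- c(kv, sprintf("P_2100_within_projection_range=%s", un$within),
            sprintf("P_2100_margin=%.6g", un$margin))
  }
  if (!is.null(obs)) {
    for (v in c("log10", "relative")) {
      fit <- fit_distance(traj, obs, v)
      kv <- c(kv, sprintf("d_avg_%s=%.6g", v, fit$d_avg))
    }
  }
  writeLines(kv, file.path(dir, "summary.txt"))
  if (plots) {
    grDevices::png(file.path(dir, "trajectory.png"), 900, 600)
    plot_trajectory(traj, obs)
    grDevices::dev.off()
    grDevices::png(file.path(dir, "elasticity.png"), 900, 600)
    plot_elasticity(traj)
    grDevices::dev.off()
  }
  invisible(dir)
}
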