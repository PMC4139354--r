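#' One annual population step
#'
#' The non-normalised discrete logistic increment
#' \eqn{\Delta P_t = r_{soc} P_t (K_t - P_t)}, in persons per year. With this
#' form `r_soc` carries units of per person per year, and historically
#' plausible growth (~1\%/yr) arises at `r_soc ~ 1e-13` once `K - P` is of
#' order 1e11 persons.
#'
#' @param P_t population, persons (> 0). Vectorised.
#' @param K_t carrying capacity, persons (> 0). Vectorised.
#' @param r_soc rate, per person per year.
#' @return increment `dP_t`, persons/year; zero exactly when `P_t == K_t`.
#' @examples
#' step_population(1e9, 2e9, 1e-13) # 1e5
#' @export
step_population <- function(P_t, K_t, r_soc) {
  if (!all(is.finite(P_t)) || !all(is.finite(K_t)) || !all(is.finite(r_soc))) {
    state_error("non-finite state passed to step_population")
  }
  if (any(P_t <= 0) || any(K_t <= 0)) {
    state_error("step_population requires P_t > 0 and K_t > 0")
  }
  r_soc * P_t * (K_t - P_t)
}

#' Carrying-capacity increment under a given cost law
#'
#' Computes \eqn{\Delta K_t} from the pre-step state and the population
#' increment, for any law in [model_laws()]. The OC case is
#' \eqn{\Delta K = (L/P_t)\,\Delta P_t}; consumption-cost variants subtract a
#' nonlinear cost term (see [model_laws()] for each form). With `a = 0` every
#' variant returns the OC value bit-for-bit.
#'
#' @param law law identifier (any non-Verhulst member of [model_laws()]).
#' @param P_t,K_t pre-step state, persons.
#' @param dP_t population increment, persons/year.
#' @param structure list with elements `L`, `a`, `b`.
#' @return increment `dK_t`, persons/year.
#' @examples
#' elasticity_and_dK("oc", 1e9, 2e9, 1e5, list(L = 1e10, a = 0, b = 0)) # 1e6
#' @export
elasticity_and_dK <- function(law, P_t, K_t, dP_t, structure) {
  if (identical(law, "verhulst")) return(rep(0, length(P_t)))
  code <- .law_code(law)
  L <- structure$L
  a <- structure$a
  b <- structure$b
  if (!is.numeric(L) || !(L > 0)) config_error("structure$L must be > 0")
  if (.is_cc(law)) {
    if (!is.numeric(a) || a < 0) config_error("structure$a must be >= 0")
    if (!is.numeric(b) || b < 0 || b > 3) config_error("structure$b in [0,3]")
  }
  if (any(P_t <= 0) || any(K_t <= 0)) {
    state_error("elasticity_and_dK requires P_t > 0 and K_t > 0")
  }
  switch(law,
    oc = (L / P_t) * dP_t,
    cc_i = (L / P_t - a * P_t^b) * dP_t,
    cc_ii = ((L - a * P_t^b) / P_t) * dP_t,
    cc_iii = (L / P_t) * dP_t - a * P_t^b,
    cc_iv = (L / P_t) * dP_t - a * K_t^b,
    cc_m = (L / P_t - a * (1e6)^(1 - b) * P_t^b) * dP_t
  )
}

#' Run the coupled annual recursion
#'
#' Simulates the model from `spec$t0` to `spec$t_end` at annual steps. The
#' increments recorded at year `t` are those applied from `t` to `t + 1`;
#' cost/elasticity terms are evaluated at the pre-step state (unless the spec
#' says `elasticity_at = "post"`). If the state becomes non-positive or
#' non-finite the trajectory is truncated at the last valid year and a
#' `collapse` event is recorded; collapse is a result, not an error.
#'
#' @param spec a [model_spec()].
#' @return `ccpop_trajectory`: list with `spec`, `points` (data.frame with
#'   columns `year`, `P`, `K`, `dP`, `dK`, `c_realized`, `pct_growth`) and
#'   `collapse` (`NULL`, or list with `year` and `reason`). `c_realized` is
#'   `dK/dP`, reported as `NA` where `dP == 0`; `pct_growth` is
#'   `100 * dP / P` in percent per year.
#' @examples
#' tr <- simulate_model(model_spec("oc", P0 = 2.25e8, K0 = 2.5e8,
#'                                 r_soc = 1e-13, L = 5e9, t_end = 100))
#' head(tr$points)
#' @export
simulate_model <- function(spec) {
  if (!inherits(spec, "ccpop_spec")) config_error("spec must be a model_spec()")
  res <- sim_core(
    .law_code(spec$law), spec$P0, spec$K0, spec$r_soc,
    if (is.na(spec$L)) 0 else spec$L, spec$a, spec$b,
    spec$t0, spec$t_end, identical(spec$elasticity_at, "post")
  )
  n <- res$n_valid
  idx <- seq_len(n)
  dP <- res$dP[idx]
  dK <- res$dK[idx]
  P <- res$P[idx]
  c_real <- ifelse(dP == 0, NA_real_, dK / dP)
  points <- data.frame(
    year = spec$t0 + idx - 1L,
    P = P, K = res$K[idx], dP = dP, dK = dK,
    c_realized = c_real,
    pct_growth = 100 * dP / P
  )
  collapse <- NULL
  if (!is.na(res$collapse_year)) {
    collapse <- list(year = res$collapse_year, reason = res$collapse_reason)
  }
  structure(list(spec = spec, points = points, collapse = collapse),
            class = "ccpop_trajectory")
}

#' @export
print.ccpop_trajectory <- function(x, ...) {
  p <- x$points
  cat(sprintf("<ccpop trajectory: %s, %d-%d (%d years)>\n",
              x$spec$law, p$year[1], p$year[nrow(p)], nrow(p)))
  if (!is.null(x$collapse)) {
    cat(sprintf("  COLLAPSED in %d: %s\n", x$collapse$year, x$collapse$reason))
  }
  last <- p[nrow(p), ]
  cat(sprintf("  final state: P = %.5g  K = %.5g  (%.4g %%/yr)\n",
              last$P, last$K, last$pct_growth))
  invisible(x)
}

#' @export
as.data.frame.ccpop_trajectory <- function(x, ...) x$points

# Population (and state) at a given year; NA if outside the retained range.
trajectory_at <- function(traj, year, what = "P") {
  i <- match(year, traj$points$year)
  if (is.na(i)) return(NA_real_)
  traj$points[[what]][i]
}

#' Closed-form Verhulst logistic solution
#'
#' Continuous-time solution of \eqn{dP/dt = r_{soc} P (K - P)}:
#' \deqn{P(t) = K / (1 + (K/P_0 - 1) e^{-r_{soc} K t}),}
#' used as a small-step oracle for the discrete simulator. The effective
#' exponential rate is `r_soc * K`. For `P0 > K` the same expression gives the
#' monotone-decreasing branch approaching `K` from above.
#'
#' @param P0 initial population, persons (> 0).
#' @param K static carrying capacity, persons (> 0).
#' @param r_soc rate, per person per year.
#' @param t years elapsed (vectorised).
#' @return population at time `t`, persons.
#' @export
verhulst_closed_form <- function(P0, K, r_soc, t) {
  stopifnot_scalar(P0, "P0", positive = TRUE)
  stopifnot_scalar(K, "K", positive = TRUE)
  K / (1 + (K / P0 - 1) * exp(-r_soc * K * t))
}

#' Conservation gap of an OC trajectory
#'
#' In the continuous limit the OC law conserves
#' \eqn{K_t - K_0 - L \ln(P_t/P_0) = 0}. The discrete recursion violates this
#' by at most \eqn{L \sum_s (\Delta P_s / P_s)^2}, so the gap doubles as a
#' correctness oracle and as the basis of the equilibrium prediction
#' \eqn{P^* = K_0 + L \ln(P^*/P_0)}.
#'
#' @param traj an OC `ccpop_trajectory` without collapse.
#' @return list with `gap` (max over years of the absolute invariant
#'   violation, persons), `bound` (the summed-step bound, persons), and
#'   `rel_gap` (gap relative to final `K`).
#' @export
oc_conservation_gap <- function(traj) {
  if (!inherits(traj, "ccpop_trajectory")) {
    config_error("traj must be a ccpop_trajectory")
  }
  if (traj$spec$law != "oc") {
    state_error("the conservation invariant holds only for the OC law")
  }
  if (!is.null(traj$collapse)) {
    state_error("trajectory collapsed; conservation gap undefined")
  }
  p <- traj$points
  L <- traj$spec$L
  pred <- traj$spec$K0 + L * log(p$P / traj$spec$P0)
  gap <- max(abs(p$K - pred))
  n <- nrow(p)
  bound <- L * sum((p$dP[-n] / p$P[-n])^2)
  list(gap = gap, bound = bound, rel_gap = gap / p$K[n])
}

#' Write / read a trajectory as CSV
#'
#' One row per year with columns `year, P, K, dP, dK, c_realized, pct_growth`
#' and a mandatory header. Missing `c_realized` (years with `dP = 0`) is
#' written as an empty field.
#'
#' @param traj a `ccpop_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns the points data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj$points, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  read.csv(path)
}
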