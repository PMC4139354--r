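#' Dynamical laws available to the simulator
#'
#' @description
#' Registry of model identifiers:
#' \describe{
#'   \item{`"verhulst"`}{static carrying capacity, \eqn{\Delta K = 0}.}
#'   \item{`"oc"`}{original coupled law, \eqn{\Delta K = (L/P)\,\Delta P}.}
#'   \item{`"cc_i"`}{\eqn{c_t = L/P - a P^b}, \eqn{\Delta K = c_t \Delta P}.}
#'   \item{`"cc_ii"`}{\eqn{c_t = (L - a P^b)/P}, \eqn{\Delta K = c_t \Delta P}.}
#'   \item{`"cc_iii"`}{\eqn{\Delta K = (L/P)\Delta P - a P^b} (flow cost).}
#'   \item{`"cc_iv"`}{\eqn{\Delta K = (L/P)\Delta P - a K^b} (stock cost).}
#'   \item{`"cc_m"`}{\eqn{c_t = L/P - a\,(10^6)^{1-b} P^b}, i.e. the
#'     consumption-cost term computed with population expressed in millions:
#'     \eqn{c_t = L/P - a\,P\,(P/10^6)^{b-1}}. This is the variant selected by
#'     [identify_cost_law()] against the bundled benchmark endpoints, and the
#'     default consumption-cost law.}
#' }
#' Every cost law reduces bit-for-bit to `"oc"` at `a = 0`.
#'
#' @return `model_laws()`: character vector of all law identifiers.
#'   `cc_candidates()`: the consumption-cost subset, in deterministic registry
#'   order (used for tie-breaking during identification).
#' @export
model_laws <- function() {
  c("verhulst", "oc", "cc_i", "cc_ii", "cc_iii", "cc_iv", "cc_m")
}

#' @rdname model_laws
#' @export
cc_candidates <- function() {
  c("cc_i", "cc_ii", "cc_iii", "cc_iv", "cc_m")
}

.law_code <- function(law) {
  code <- match(law, model_laws()) - 1L
  if (is.na(code)) {
    config_error(sprintf(
      "unknown law '%s' (known: %s)", law, paste(model_laws(), collapse = ", ")
    ))
  }
  code
}

.is_cc <- function(law) startsWith(law, "cc_")

#' Specify one model run
#'
#' Bundles the dynamical law, rate and structural parameters, initial
#' conditions, and the time window for a single simulation.
#'
#' @param law model identifier, see [model_laws()].
#' @param P0 initial population at year `t0`, persons (> 0).
#' @param K0 initial carrying capacity, persons (> `P0`).
#' @param r_soc socially mediated intrinsic rate, per person per year (> 0).
#'   This is the only rate entering the recursion.
#' @param L limit to economies of scale, persons (> 0). Ignored by
#'   `"verhulst"`.
#' @param a consumption-cost discount coefficient (>= 0). `a = 0` reduces any
#'   cost law to `"oc"` exactly. Ignored by `"verhulst"` and `"oc"`.
#' @param b consumption-cost power (0 <= b <= 3). Ignored as for `a`.
#' @param t0,t_end calendar years CE delimiting the run (integers,
#'   `t_end > t0`). Defaults 1 and 2500.
#' @param r_max optional natural maximum intrinsic rate, per capita per year.
#'   Bookkeeping only: it never enters the recursion, but when supplied the
#'   dilution ("Marx") parameter `m = r_max / r_soc` is derived and must be
#'   >= 1.
#' @param elasticity_at `"pre"` (default) evaluates the elasticity/cost terms
#'   at the pre-step population `P_t`; `"post"` substitutes `P_t + dP_t`.
#'   Calibration of `K0` absorbs most of the difference between the two
#'   conventions.
#'
#' @return An object of class `ccpop_spec`.
#' @examples
#' spec <- model_spec("oc", P0 = 2.25e8, K0 = 2.5e8, r_soc = 1e-13, L = 5e9)
#' spec
#' @export
model_spec <- function(law = "oc", P0, K0, r_soc, L = NA_real_,
                       a = 0, b = 0, t0 = 1L, t_end = 2500L,
                       r_max = NULL, elasticity_at = c("pre", "post")) {
  law <- match.arg(law, model_laws())
  elasticity_at <- match.arg(elasticity_at)
  stopifnot_scalar(P0, "P0", positive = TRUE)
  stopifnot_scalar(K0, "K0", positive = TRUE)
  stopifnot_scalar(r_soc, "r_soc", positive = TRUE)
  if (law == "verhulst") {
    # the static-K baseline admits the exact fixed point P0 = K0
    if (K0 < P0) config_error("K0 must be >= P0")
  } else if (K0 <= P0) {
    config_error("K0 must be strictly greater than P0")
  }
  t0 <- as.integer(t0)
  t_end <- as.integer(t_end)
  if (is.na(t0) || is.na(t_end) || t_end <= t0) {
    config_error("t0 and t_end must be integers with t_end > t0")
  }
  if (law != "verhulst") {
    stopifnot_scalar(L, "L", positive = TRUE)
  }
  if (.is_cc(law)) {
    stopifnot_scalar(a, "a")
    stopifnot_scalar(b, "b")
    if (a < 0) config_error("a must be >= 0")
    if (b < 0 || b > 3) config_error("b must lie in [0, 3]")
  } else {
    a <- 0
    b <- 0
  }
  m <- NA_real_
  if (!is.null(r_max)) {
    stopifnot_scalar(r_max, "r_max", positive = TRUE)
    m <- r_max / r_soc
    if (m < 1) config_error("r_max implies m = r_max/r_soc < 1")
  }
  structure(
    list(
      law = law, P0 = P0, K0 = K0, r_soc = r_soc,
      L = if (law == "verhulst") NA_real_ else L,
      a = a, b = b, t0 = t0, t_end = t_end,
      r_max = if (is.null(r_max)) NA_real_ else r_max, m = m,
      elasticity_at = elasticity_at
    ),
    class = "ccpop_spec"
  )
}

#' @export
print.ccpop_spec <- function(x, ...) {
  cat("<ccpop model spec>\n")
  cat(sprintf("  law: %s   years: %d-%d (%s-step elasticity)\n",
              x$law, x$t0, x$t_end, x$elasticity_at))
  cat(sprintf("  P0 = %.6g  K0 = %.6g  r_soc = %.6g\n", x$P0, x$K0, x$r_soc))
  if (x$law != "verhulst") cat(sprintf("  L = %.6g", x$L))
  if (.is_cc(x$law)) cat(sprintf("  a = %.6g  b = %.6g", x$a, x$b))
  if (x$law != "verhulst") cat("\n")
  if (!is.na(x$m)) cat(sprintf("  r_max = %.6g (m = %.4g)\n", x$r_max, x$m))
  invisible(x)
}

# Replace fields of a spec, revalidating.
update_spec <- function(spec, ...) {
  fields <- list(...)
  s <- unclass(spec)
  for (nm in names(fields)) s[[nm]] <- fields[[nm]]
  model_spec(
    law = s$law, P0 = s$P0, K0 = s$K0, r_soc = s$r_soc, L = s$L,
    a = s$a, b = s$b, t0 = s$t0, t_end = s$t_end,
    r_max = if (is.na(s$r_max)) NULL else s$r_max,
    elasticity_at = s$elasticity_at
  )
}
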