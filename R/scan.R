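# Sensitivity-scan protocol: L-scan for the OC law, coarse-then-fine (a, b)
# grid for consumption-cost laws, and the cost-law identification harness.

# Build one ScanRecord row for a calibrated spec.
.scan_record <- function(spec, K0, obs, variant, pass = NA_character_) {
  traj <- simulate_model(update_spec(spec, K0 = K0))
  fit <- fit_distance(traj, obs, variant)
  p <- function(y) trajectory_at(traj, y)
  data.frame(
    law = spec$law, P0 = spec$P0, r_soc = spec$r_soc,
    L = spec$L, a = spec$a, b = spec$b, K0 = K0,
    d_avg = fit$d_avg, comparable = fit$comparable,
    P_1800 = p(1800), P_2012 = p(2012), P_2100 = p(2100), P_2500 = p(2500),
    pct_error_2012 = if (is.na(p(2012))) NA_real_ else
      100 * (p(2012) - 7.00e9) / 7.00e9,
    pass = pass,
    stringsAsFactors = FALSE
  )
}

# Calibrate K0 for a spec against an anchor, returning NA on bracketing
# failure instead of erroring (scans record such points as incomparable).
.try_K0 <- function(spec, anchor_year, anchor_value) {
  tryCatch(
    calibrate_K0(spec, anchor_year, anchor_value)$K0,
    ccpop_error = function(e) NA_real_
  )
}

.empty_record <- function(spec, pass = NA_character_) {
  data.frame(
    law = spec$law, P0 = spec$P0, r_soc = spec$r_soc,
    L = spec$L, a = spec$a, b = spec$b, K0 = NA_real_,
    d_avg = NA_real_, comparable = FALSE,
    P_1800 = NA_real_, P_2012 = NA_real_, P_2100 = NA_real_,
    P_2500 = NA_real_, pct_error_2012 = NA_real_, pass = pass,
    stringsAsFactors = FALSE
  )
}

#' Scan the limit to economies of scale
#'
#' For each `L` in the grid, recalibrates `K0` against the anchor, simulates
#' the full trajectory, and records the fit distance and the 1800/2012/2100/
#' 2500 CE populations. The default anchor policy re-anchors every `L` on the
#' same 1800 CE value (either a supplied benchmark value, or the aggregate
#' observation at the anchor year), which is what makes the d_avg-versus-L
#' curve reproducible.
#'
#' @param case list or one-row data.frame with `P0` and `r_soc`.
#' @param L_grid numeric vector of `L` values, persons (envelope
#'   5e9–2e11 for benchmark replication).
#' @param obs a `ccpop_observations` used for the fit distance (and for the
#'   default anchor value).
#' @param law law identifier, default `"oc"`.
#' @param a,b cost coefficients when `law` is a consumption-cost variant.
#' @param anchor_year anchor year, default 1800.
#' @param anchor_value anchor population, persons; default the aggregate
#'   observation at `anchor_year`.
#' @param variant fit-metric variant, see [fit_distance()].
#' @return data.frame of scan records, sorted by `L`; rows whose calibration
#'   fails or whose trajectory collapses before coverage carry
#'   `comparable = FALSE`.
#' @export
scan_L <- function(case, L_grid, obs, law = "oc", a = 0, b = 0,
                   anchor_year = 1800L, anchor_value = NULL,
                   variant = c("log10", "relative")) {
  variant <- match.arg(variant)
  L_grid <- sort(unique(L_grid))
  if (is.null(anchor_value)) {
    anchor_value <- obs_at(obs, anchor_year)
    if (is.na(anchor_value)) {
      config_error("no aggregate observation at the anchor year")
    }
  }
  rows <- lapply(L_grid, function(L) {
    spec <- model_spec(law, P0 = case$P0, K0 = 2 * case$P0,
                       r_soc = case$r_soc, L = L, a = a, b = b)
    K0 <- .try_K0(spec, anchor_year, anchor_value)
    if (is.na(K0)) .empty_record(spec) else
      .scan_record(spec, K0, obs, variant)
  })
  do.call(rbind, rows)
}

#' Best row of a scan
#'
#' Deterministic argmin of `d_avg` over comparable records (first row on
#' exact ties, i.e. grid order).
#'
#' @param records a scan data.frame from [scan_L()] or [scan_ab()].
#' @return the minimising row (one-row data.frame).
#' @export
scan_best <- function(records) {
  ok <- which(records$comparable & is.finite(records$d_avg))
  if (!length(ok)) data_error("no comparable records in scan")
  records[ok[which.min(records$d_avg)], , drop = FALSE]
}

#' Coarse-then-fine scan of the consumption-cost coefficients
#'
#' Holds `L` fixed (the case's best OC value, per the protocol), crosses a
#' coarse grid of `a` (whole orders of magnitude) with `b` from 0.1 to 2.5 in
#' steps of 0.1, then refines around the coarse minimiser: `b` in steps of
#' `fine_step` within ±0.1, `a` at {1/5, 1/2, 1, 2, 5} times the coarse
#' minimiser. All records (both passes) are returned.
#'
#' @inheritParams scan_L
#' @param L fixed limit to economies of scale, persons.
#' @param a_grid coarse `a` values; default `10^seq(-16, -10)`.
#' @param b_grid coarse `b` values; default `seq(0.1, 2.5, by = 0.1)`.
#' @param refine run the fine pass (default `TRUE`).
#' @param fine_step fine-pass `b` step (default 0.01).
#' @return data.frame of scan records with a `pass` column
#'   (`"coarse"`/`"fine"`).
#' @export
scan_ab <- function(case, L, obs, law = "cc_m",
                    a_grid = 10^seq(-16, -10), b_grid = seq(0.1, 2.5, by = 0.1),
                    refine = TRUE, fine_step = 0.01,
                    anchor_year = 1800L, anchor_value = NULL,
                    variant = c("log10", "relative")) {
  variant <- match.arg(variant)
  if (is.null(anchor_value)) {
    anchor_value <- obs_at(obs, anchor_year)
    if (is.na(anchor_value)) {
      config_error("no aggregate observation at the anchor year")
    }
  }
  one <- function(a, b, pass) {
    spec <- model_spec(law, P0 = case$P0, K0 = 2 * case$P0,
                       r_soc = case$r_soc, L = L, a = a, b = b)
    K0 <- .try_K0(spec, anchor_year, anchor_value)
    if (is.na(K0)) .empty_record(spec, pass) else
      .scan_record(spec, K0, obs, variant, pass)
  }
  grid <- expand.grid(a = sort(a_grid), b = sort(b_grid))
  coarse <- do.call(rbind, Map(one, grid$a, grid$b, "coarse"))
  out <- coarse
  if (refine) {
    best <- scan_best(coarse)
    if (best$a == 0) {
      fine_a <- 0
    } else {
      fine_a <- best$a * c(1 / 5, 1 / 2, 1, 2, 5)
    }
    fine_b <- seq(max(0, best$b - 0.1), min(3, best$b + 0.1), by = fine_step)
    fgrid <- expand.grid(a = fine_a, b = round(fine_b, 10))
    fine <- do.call(rbind, Map(one, fgrid$a, fgrid$b, "fine"))
    out <- rbind(coarse, fine)
  }
  rownames(out) <- NULL
  out
}

#' Identify the consumption-cost law against benchmark endpoints
#'
#' For each candidate cost law and each anchor row (a benchmark
#' parameterisation with its published 1800/2012/2100 CE populations),
#' calibrates `K0` so the candidate passes through the row's 1800 CE value,
#' simulates, and scores the worst relative error over the 2012 and 2100 CE
#' endpoints. The candidate minimising the worst-case error across rows is
#' selected (ties broken by candidate order). If no candidate achieves a
#' worst-case error below `tol_fail` the function fails loudly, attaching the
#' full evidence table to the error.
#'
#' @param candidates character vector of candidate laws, default
#'   [cc_candidates()].
#' @param anchors data.frame like `bundled_cases("cc")`: columns `P0`,
#'   `r_soc`, `L`, `a`, `b`, `P_1800`, `P_2012`, `P_2100`.
#' @param tol_fail loud-failure threshold on the selected candidate's
#'   worst-case relative endpoint error (default 0.05).
#' @return `ccpop_identification`: list with `selected` (law id), `worst`
#'   (its worst-case relative error), `ranking` (per-candidate worst-case
#'   errors), and `evidence` (per candidate × row: calibrated `K0`, modelled
#'   endpoints, relative errors; calibration failures carry `NA` endpoints
#'   and infinite error).
#' @export
identify_cost_law <- function(candidates = cc_candidates(),
                              anchors = bundled_cases("cc"),
                              tol_fail = 0.05) {
  if (length(candidates) < 1) config_error("need at least one candidate")
  need <- c("P0", "r_soc", "L", "a", "b", "P_1800", "P_2012", "P_2100")
  if (!all(need %in% names(anchors))) {
    config_error(sprintf("anchors must have columns %s",
                         paste(need, collapse = ", ")))
  }
  rows <- lapply(candidates, function(law) {
    do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
      an <- anchors[i, ]
      spec <- model_spec(law, P0 = an$P0, K0 = 2 * an$P0, r_soc = an$r_soc,
                         L = an$L, a = an$a, b = an$b, t_end = 2100L)
      K0 <- .try_K0(spec, 1800L, an$P_1800)
      if (is.na(K0)) {
        return(data.frame(candidate = law, row = i, K0 = NA_real_,
                          P_2012 = NA_real_, P_2100 = NA_real_,
                          err_2012 = Inf, err_2100 = Inf,
                          stringsAsFactors = FALSE))
      }
      traj <- simulate_model(update_spec(spec, K0 = K0))
      p12 <- trajectory_at(traj, 2012)
      p21 <- trajectory_at(traj, 2100)
      e12 <- if (is.na(p12)) Inf else abs(p12 - an$P_2012) / an$P_2012
      e21 <- if (is.na(p21)) Inf else abs(p21 - an$P_2100) / an$P_2100
      data.frame(candidate = law, row = i, K0 = K0,
                 P_2012 = p12, P_2100 = p21,
                 err_2012 = e12, err_2100 = e21, stringsAsFactors = FALSE)
    }))
  })
  evidence <- do.call(rbind, rows)
  worst <- vapply(candidates, function(law) {
    e <- evidence[evidence$candidate == law, ]
    max(c(e$err_2012, e$err_2100))
  }, numeric(1))
  sel <- which.min(worst) # ties: first in candidate order
  result <- structure(
    list(selected = candidates[sel], worst = worst[[sel]],
         ranking = setNames(worst, candidates), evidence = evidence),
    class = "ccpop_identification"
  )
  if (!(worst[[sel]] < tol_fail)) {
    msg <- paste0(
      "no candidate cost law reproduces the anchor endpoints within ",
      sprintf("%.0f%%", 100 * tol_fail), "; worst-case errors: ",
      paste(sprintf("%s = %.3g", candidates, worst), collapse = ", "),
      "\n", paste(capture.output(print(evidence)), collapse = "\n")
    )
    cond <- structure(
      class = c("ccpop_identification_failure", "ccpop_error",
                "error", "condition"),
      list(message = msg, call = sys.call(-1), evidence = evidence)
    )
    stop(cond)
  }
  result
}

#' @export
print.ccpop_identification <- function(x, ...) {
  cat(sprintf("<ccpop cost-law identification: selected '%s' (worst-case endpoint error %.3g%%)>\n",
              x$selected, 100 * x$worst))
  cat("  ranking:\n")
  for (nm in names(x$ranking)) {
    cat(sprintf("    %-7s %s\n", nm,
                ifelse(is.finite(x$ranking[[nm]]),
                       sprintf("%.4g%%", 100 * x$ranking[[nm]]), "collapsed")))
  }
  invisible(x)
}
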