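# Shared test helpers.

# Plain-R reference recursion, independent of the compiled simulator.
# Deliberately mirrors the two-column "spreadsheet" construction.
oracle_recursion <- function(law, P0, K0, r, L = 0, a = 0, b = 0,
                             t0 = 1, t_end = 11) {
  n <- t_end - t0 + 1
  P <- K <- numeric(n)
  p <- P0
  k <- K0
  for (i in seq_len(n)) {
    P[i] <- p
    K[i] <- k
    dp <- r * p * (k - p)
    dk <- switch(law,
      verhulst = 0,
      oc = (L / p) * dp,
      cc_i = (L / p - a * p^b) * dp,
      cc_ii = ((L - a * p^b) / p) * dp,
      cc_iii = (L / p) * dp - a * p^b,
      cc_iv = (L / p) * dp - a * k^b,
      cc_m = (L / p - a * (1e6)^(1 - b) * p^b) * dp
    )
    p <- p + dp
    k <- k + dk
    if (!(p > 0) || !(k > 0) || !is.finite(p) || !is.finite(k)) {
      return(data.frame(year = (t0:t_end)[seq_len(i)], P = P[seq_len(i)],
                        K = K[seq_len(i)]))
    }
  }
  data.frame(year = t0:t_end, P = P, K = K)
}

read_golden <- function(name) {
  path <- test_path(name)
  cfg_lines <- grep("^#", readLines(path), value = TRUE)
  kv <- strsplit(sub("^# ", "", cfg_lines), "=", fixed = TRUE)
  cfg <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  num <- setdiff(names(cfg), "law")
  cfg[num] <- lapply(cfg[num], as.numeric)
  list(config = cfg, points = read.csv(path, comment.char = "#"))
}

golden_spec <- function(g) {
  model_spec(g$config$law, P0 = g$config$P0, K0 = g$config$K0,
             r_soc = g$config$r, L = g$config$L, a = g$config$a,
             b = g$config$b, t0 = g$config$t0, t_end = g$config$t_end)
}

# A small OC spec used across tests.
tiny_oc <- function(t_end = 2500L, ...) {
  model_spec("oc", P0 = 2.25e8, K0 = 2.5e8, r_soc = 1e-13, L = 5e9,
             t_end = t_end, ...)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
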