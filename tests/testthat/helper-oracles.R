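# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the implementation under test.

# Life expectancy at birth by fine-step numerical integration of the
# survival function of a piecewise-constant hazard (trapezoid rule on the
# closed intervals, exact exponential tail on the open interval).
oracle_e0_integration <- function(sched, step = 0.001) {
  k <- nrow(sched)
  S <- 1
  e0 <- 0
  for (i in seq_len(k - 1L)) {
    n <- sched$width[i]
    m <- sched$m[i]
    tt <- seq(0, n, by = step)
    Sv <- S * exp(-m * tt)
    e0 <- e0 + sum((Sv[-1L] + Sv[-length(Sv)]) / 2) * step
    S <- S * exp(-m * n)
  }
  e0 + S / sched$m[k]
}

# Exhaustive search over all contiguous partitions of the sorted values
# into k classes: returns the minimal within-class sum of squared
# deviations. Feasible for small n (C(n-1, k-1) partitions).
oracle_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1L) return(ssd(x))
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (col in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, col], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ssd(x[(b[i] + 1L):b[i + 1L]])
    if (tot < best) best <- tot
  }
  best
}

# Least-squares-with-entity-dummies (LSDV) fit via stats::lm; the within
# estimator must reproduce its slope coefficients and classical SEs.
oracle_lsdv <- function(formula, data, entity = "province") {
  rhs <- paste(attr(stats::terms(formula), "term.labels"), collapse = " + ")
  lhs <- all.vars(formula)[1L]
  f2 <- stats::as.formula(paste(lhs, "~", rhs, "+ factor(", entity, ")"))
  fit <- stats::lm(f2, data = data)
  sm <- summary(fit)$coefficients
  keep <- !grepl("factor\\(", rownames(sm)) &
    rownames(sm) != "(Intercept)"
  sm[keep, , drop = FALSE]
}

# Small complete panel fixture used by several files: 4 provinces from
# the roster, 3 waves, 3 indicator codes.
toy_panel <- function() {
  provs <- c("Beijing", "Tianjin", "Hebei", "Shanxi")
  waves <- c(2005L, 2010L, 2015L)
  grid <- expand.grid(province = provs, year = waves,
                      code = c("ALE", "DR", "AYE"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(99)
  grid$value <- round(stats::runif(nrow(grid), 1, 100), 3)
  as_panel(grid)
}
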