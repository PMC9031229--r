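#' Min-max standardization with indicator polarity
#'
#' Rescales a raw indicator column to \code{[0, 1]} over its
#' standardization pool. Benefit-type (positive) indicators use
#' \code{(x - x_min) / (x_max - x_min)}; cost-type (negative) indicators
#' are direction-reversed: \code{(x_max - x) / (x_max - x_min)}, so that
#' 1 always means "best". A constant column carries no ordering
#' information and is mapped to the index midpoint 0.5 with a warning.
#'
#' @param x Numeric vector (length >= 1, finite).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return Numeric vector in \code{[0, 1]}, same length as \code{x}, with
#'   attributes \code{x_min}, \code{x_max} and \code{polarity}.
#' @export
#' @examples
#' standardize_minmax(c(1, 3, 5), "positive")   # 0, 0.5, 1
standardize_minmax <- function(x, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (length(x) == 0L) stop("empty column")
  if (any(!is.finite(x))) stop("non-finite values in column")
  x_min <- min(x); x_max <- max(x)
  if (x_max == x_min) {
    warning("constant column: standardized to midpoint 0.5")
    p <- rep(0.5, length(x))
  } else if (polarity == "positive") {
    p <- (x - x_min) / (x_max - x_min)
  } else {
    p <- (x_max - x) / (x_max - x_min)
  }
  attr(p, "x_min") <- x_min
  attr(p, "x_max") <- x_max
  attr(p, "polarity") <- polarity
  p
}

#' Standardize an observation-by-indicator matrix
#'
#' Applies [standardize_minmax()] column-wise, using each code's polarity
#' from the registry. The result retains per-column extremes and polarity
#' so the standardization is auditable.
#'
#' @param mat Numeric matrix, rows = (province, year) observations,
#'   columns = indicator codes (colnames required).
#' @param registry Registry data.frame with \code{code} and
#'   \code{polarity} columns; defaults to [indicator_registry()].
#' @return Matrix of class \code{"std_matrix"} with all cells in
#'   \code{[0, 1]} and attributes \code{x_min}, \code{x_max},
#'   \code{polarity} (named per column).
#' @export
standardize_matrix <- function(mat, registry = indicator_registry()) {
  if (is.null(colnames(mat))) stop("matrix must have code colnames")
  pol <- registry$polarity[match(colnames(mat), registry$code)]
  if (anyNA(pol))
    stop("codes missing from registry: ",
         paste(colnames(mat)[is.na(pol)], collapse = ", "))
  out <- mat
  xmin <- xmax <- stats::setNames(numeric(ncol(mat)), colnames(mat))
  for (j in seq_len(ncol(mat))) {
    p <- standardize_minmax(mat[, j], pol[j])
    out[, j] <- p
    xmin[j] <- attr(p, "x_min"); xmax[j] <- attr(p, "x_max")
  }
  attr(out, "x_min") <- xmin
  attr(out, "x_max") <- xmax
  attr(out, "polarity") <- stats::setNames(pol, colnames(mat))
  class(out) <- c("std_matrix", class(out))
  out
}

#' Entropy weights for a standardized indicator matrix
#'
#' Objective weighting by information divergence. For each column j of the
#' standardized matrix, the cross-observation shares
#' \code{p_ij = P_ij / sum_i(P_ij)} define a normalized Shannon entropy
#' \code{e_j = -(1/ln n) * sum_i p_ij ln p_ij} (with \code{0 ln 0 = 0});
#' the divergence \code{d_j = 1 - e_j} measures how much the indicator
#' discriminates between observations, and weights are
#' \code{w_j = d_j / sum_j d_j}. A constant column (including all-zero)
#' carries no information: it gets \code{e = 1}, \code{d = 0}, \code{w = 0}.
#'
#' An epsilon-offset mode is available for cross-checking against
#' implementations that add a small constant to shares before taking logs
#' instead of using the exact \code{0 ln 0 = 0} convention.
#'
#' @param P Standardized matrix (cells >= 0, >= 2 rows), typically from
#'   [standardize_matrix()].
#' @param codes Optional subset of columns to weight (default: all).
#' @param zero_share Either \code{"exact"} (default; \code{0 ln 0 = 0}) or
#'   a small positive number added to every cell before computing shares.
#' @return data.frame of class \code{"entropy_weights"} with columns
#'   \code{code}, \code{entropy}, \code{divergence}, \code{weight};
#'   attribute \code{"pool_n"} records the pooling scope (number of
#'   observations).
#' @export
#' @examples
#' P <- cbind(A = c(0, 1), B = c(0.5, 0.5))
#' entropy_weights(P)   # weights 1 and 0
entropy_weights <- function(P, codes = colnames(P), zero_share = "exact") {
  P <- as.matrix(P)[, codes, drop = FALSE]
  if (nrow(P) < 2L) stop("need at least 2 observations")
  if (any(P < 0)) stop("standardized cells must be non-negative")
  if (!identical(zero_share, "exact")) {
    eps <- as.numeric(zero_share)
    if (!is.finite(eps) || eps <= 0) stop("zero_share must be 'exact' or > 0")
    P <- P + eps
  }
  n <- nrow(P)
  e <- vapply(seq_len(ncol(P)), function(j) {
    col <- P[, j]
    tot <- sum(col)
    if (tot == 0 || max(col) == min(col)) return(1)  # no information
    p <- col / tot
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(n)
  }, numeric(1))
  d <- 1 - e
  # guard tiny negative round-off
  d[d < 0 & d > -1e-12] <- 0
  if (sum(d) <= 0)
    stop("no discriminating information: all columns constant")
  w <- d / sum(d)
  out <- data.frame(code = colnames(P), entropy = e, divergence = d,
                    weight = w, stringsAsFactors = FALSE)
  attr(out, "pool_n") <- n
  class(out) <- c("entropy_weights", "data.frame")
  out
}

#' @export
print.entropy_weights <- function(x, digits = 4, ...) {
  cat("Entropy weights over", attr(x, "pool_n"), "observations,",
      nrow(x), "indicators\n")
  tab <- as.data.frame(x)
  tab[-1L] <- lapply(tab[-1L], round, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Aggregate standardized indicators into composite scores
#'
#' Computes the weighted sum \code{score_i = sum_j w_j X_ij} over a scope
#' of codes. For dimension sub-scores the scope's weights are renormalized
#' to sum to 1, so each dimension score lives on the same \code{[0, 1]}
#' scale as the overall index.
#'
#' @param P Standardized matrix.
#' @param weights An [entropy_weights()] table (or data.frame with
#'   \code{code} and \code{weight}).
#' @param scope Codes to aggregate over; default all weighted codes.
#' @param renormalize Renormalize the scope's weights to sum to 1 (used
#'   for dimension sub-scores). Default \code{FALSE}.
#' @return Named numeric vector of scores, one per row of \code{P}.
#' @export
aggregate_scores <- function(P, weights, scope = weights$code,
                             renormalize = FALSE) {
  if (!all(scope %in% weights$code))
    stop("scope codes absent from weights: ",
         paste(setdiff(scope, weights$code), collapse = ", "))
  if (!all(scope %in% colnames(P)))
    stop("scope codes absent from matrix: ",
         paste(setdiff(scope, colnames(P)), collapse = ", "))
  w <- weights$weight[match(scope, weights$code)]
  if (renormalize) {
    if (sum(w) <= 0) stop("scope has zero total weight")
    w <- w / sum(w)
  }
  drop(as.matrix(P)[, scope, drop = FALSE] %*% w)
}

#' Score a full province-year panel: dimension and overall QoL indices
#'
#' End-to-end composite-index construction: reshapes the panel to an
#' observation-by-indicator matrix, min-max standardizes with polarity,
#' computes entropy weights, and aggregates into the three dimension
#' scores (health \code{B1}, participation \code{B2}, security \code{B3},
#' each with within-dimension renormalized weights) and the overall index
#' \code{A} (all 16 indicators, global weights).
#'
#' With \code{pooling = "pooled"} (default) all province-year observations
#' form one standardization and weighting pool, placing every wave on a
#' common scale so index levels are comparable over time. With
#' \code{"per_wave"} each wave is standardized and weighted on its own,
#' which is the natural choice for purely cross-sectional ranking but
#' makes levels incomparable across waves.
#'
#' @param panel A complete \code{qol_panel} of the 16 indicators.
#' @param registry Indicator registry; defaults to [indicator_registry()].
#' @param pooling \code{"pooled"} or \code{"per_wave"}.
#' @param zero_share Passed to [entropy_weights()].
#' @return data.frame of class \code{"qol_scores"} with columns
#'   \code{province}, \code{year}, \code{B1}, \code{B2}, \code{B3},
#'   \code{A}; attributes \code{"weights"} (the [entropy_weights()] table,
#'   or a list of per-wave tables) and \code{"pooling"}.
#' @export
score_panel <- function(panel, registry = indicator_registry(),
                        pooling = c("pooled", "per_wave"),
                        zero_share = "exact") {
  pooling <- match.arg(pooling)
  codes <- registry$code
  obs <- unique(panel[c("province", "year")])
  obs <- obs[order(obs$year, match(obs$province, province_roster())), ]
  score_block <- function(block_obs) {
    mat <- panel_to_matrix(panel, codes, block_obs)
    P <- standardize_matrix(mat, registry)
    w <- entropy_weights(P, zero_share = zero_share)
    dims <- split(registry$code, registry$dimension)
    sc <- data.frame(
      province = block_obs$province, year = block_obs$year,
      B1 = aggregate_scores(P, w, dims$health, renormalize = TRUE),
      B2 = aggregate_scores(P, w, dims$participation, renormalize = TRUE),
      B3 = aggregate_scores(P, w, dims$security, renormalize = TRUE),
      A = aggregate_scores(P, w),
      stringsAsFactors = FALSE, row.names = NULL
    )
    list(scores = sc, weights = w)
  }
  if (pooling == "pooled") {
    res <- score_block(obs)
    scores <- res$scores
    weights <- res$weights
  } else {
    parts <- lapply(split(obs, obs$year), score_block)
    scores <- do.call(rbind, lapply(parts, `[[`, "scores"))
    rownames(scores) <- NULL
    weights <- lapply(parts, `[[`, "weights")
  }
  attr(scores, "weights") <- weights
  attr(scores, "pooling") <- pooling
  class(scores) <- c("qol_scores", "data.frame")
  scores
}

#' @export
print.qol_scores <- function(x, ...) {
  cat("QoL scores:", nrow(x), "province-year observations (pooling:",
      attr(x, "pooling"), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' @export
summary.qol_scores <- function(object, scheme = region_scheme(), ...) {
  reg <- scheme[object$province]
  agg <- function(subset_idx, label) {
    s <- object[subset_idx, ]
    do.call(rbind, lapply(split(s, s$year), function(b) data.frame(
      group = label, year = b$year[1L], mean_A = mean(b$A),
      max_A = max(b$A), max_province = b$province[which.max(b$A)],
      min_A = min(b$A), min_province = b$province[which.min(b$A)],
      stringsAsFactors = FALSE)))
  }
  out <- agg(rep(TRUE, nrow(object)), "national")
  for (r in c("east", "central", "west", "northeast"))
    out <- rbind(out, agg(reg == r, r))
  rownames(out) <- NULL
  class(out) <- c("summary.qol_scores", "data.frame")
  out
}

#' @export
print.summary.qol_scores <- function(x, ...) {
  cat("National and regional QoL index summary\n")
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "year"
  tab[num] <- lapply(tab[num], round, digits = 4)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Write scores and weights as delimited text
#'
#' @param scores A \code{qol_scores} object.
#' @param scores_path,weights_path Output CSV paths; the weights file
#'   includes entropy, divergence and weight per code.
#' @param seed Optional seed recorded in provenance headers.
#' @return Invisibly, the score path.
#' @export
write_scores <- function(scores, scores_path, weights_path = NULL,
                         seed = NULL) {
  write_panel(as.data.frame(scores), scores_path, seed = seed)
  if (!is.null(weights_path)) {
    w <- attr(scores, "weights")
    if (is.data.frame(w)) {
      write_panel(as.data.frame(w), weights_path, seed = seed)
    } else {
      tabs <- Map(function(tab, yr) cbind(year = yr, as.data.frame(tab)),
                  w, names(w))
      write_panel(do.call(rbind, tabs), weights_path, seed = seed)
    }
  }
  invisible(scores_path)
}
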