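#' Coefficient of variation
#'
#' Dispersion relative to the mean: sample standard deviation (n - 1
#' denominator) divided by the mean. The standard regional-inequality
#' measure for positive-valued scores: the larger the CV, the stronger the
#' spatial difference, and it is invariant to rescaling all values by a
#' common positive factor.
#'
#' @param values Numeric vector, length >= 2, with positive mean.
#' @return Non-negative scalar.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4, 6))  # 0.5
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation requires mean > 0")
  stats::sd(values) / m
}

#' Regional disparity table of the coefficient of variation
#'
#' Computes the CV of each score kind (\code{B1}, \code{B2}, \code{B3},
#' \code{A}) per year, nationally (all 31 provinces) and within each of
#' the four regions (member provinces only).
#'
#' @param scores A \code{qol_scores} object (or data.frame with columns
#'   \code{province}, \code{year} and the score kinds).
#' @param scheme Region scheme from [region_scheme()].
#' @param kinds Score columns to summarize.
#' @return data.frame with columns \code{group}, \code{year},
#'   \code{kind}, \code{cv}.
#' @export
disparity_table <- function(scores, scheme = region_scheme(),
                            kinds = c("B1", "B2", "B3", "A")) {
  reg <- scheme[scores$province]
  groups <- c(list(national = rep(TRUE, nrow(scores))),
              lapply(stats::setNames(nm = c("east", "central", "west",
                                            "northeast")),
                     function(r) reg == r))
  rows <- list()
  for (g in names(groups)) {
    sub <- scores[groups[[g]], ]
    for (yr in sort(unique(sub$year))) {
      blk <- sub[sub$year == yr, ]
      for (k in kinds) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, year = yr, kind = k,
          cv = coefficient_of_variation(blk[[k]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Signed percent change between two values
#'
#' \code{100 * (v_end - v_start) / v_start}. Summaries display two
#' decimals; the value itself is returned at full precision. Note the
#' asymmetry under path reversal: a rise and the return fall differ in
#' magnitude, \code{percent_change(a, b) = -percent_change(b, a) * b / a}.
#'
#' @param v_start Baseline value, must be > 0.
#' @param v_end End value.
#' @return Signed percent (e.g. \code{4.25} for a 4.25\% rise).
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("percent change requires a positive baseline")
  100 * (v_end - v_start) / v_start
}

#' Fisher-Jenks natural breaks
#'
#' Classifies a numeric series into \code{k} classes by the natural-breaks
#' criterion: over all contiguous partitions of the sorted values,
#' minimize the total within-class sum of squared deviations from class
#' means. Solved exactly (and deterministically) by dynamic programming in
#' O(k n^2); this is the standard "natural breaking point" method of
#' thematic mapping, not a k-means heuristic.
#'
#' The returned breaks are the upper boundaries of the first \code{k - 1}
#' classes (the maximum member value of each). Classification is by
#' half-open upper intervals: a value equal to a break belongs to the
#' lower class; the last interval is closed above.
#'
#' @param values Numeric vector with at least \code{k} distinct values.
#' @param k Number of classes (default 5).
#' @return Numeric vector of \code{k - 1} strictly increasing break
#'   values, with attribute \code{"ssd"} (the optimal within-class sum of
#'   squared deviations).
#' @seealso [classify_levels()]
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)  # break at 3
jenks_breaks <- function(values, k = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  x <- sort(values)
  n <- length(x)
  if (length(unique(x)) < k)
    stop("only ", length(unique(x)), " distinct values; need >= ", k,
         " for ", k, " classes - use a smaller k")
  # Prefix sums on mean-centred data give O(1) within-segment SSD without
  # catastrophic cancellation (SSD is shift-invariant).
  xc <- x - mean(x)
  cs <- cumsum(xc); cs2 <- cumsum(xc^2)
  seg_ssd <- function(i, j) {  # SSD of x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  # D[c, j]: min SSD partitioning x[1..j] into c classes; B records the
  # start index of the last class.
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(1L, nrow = k, ncol = n)
  for (j in seq_len(n)) D[1L, j] <- seg_ssd(1L, j)
  if (k > 1L) {
    for (cls in 2L:k) {
      for (j in cls:n) {
        best <- Inf; best_i <- cls
        for (i in cls:j) {
          cand <- D[cls - 1L, i - 1L] + seg_ssd(i, j)
          if (cand < best) { best <- cand; best_i <- i }
        }
        D[cls, j] <- best
        B[cls, j] <- best_i
      }
    }
  }
  # Backtrack class boundaries.
  ends <- integer(k)
  j <- n
  for (cls in k:1L) {
    ends[cls] <- j
    j <- B[cls, j] - 1L
  }
  breaks <- x[ends[-k]]
  if (k > 2L && any(diff(breaks) <= 0))
    stop("degenerate breaks; too many tied values for k = ", k)
  # report the objective recomputed stably from the chosen partition
  bounds <- c(0L, ends)
  ssd <- 0
  for (cls in seq_len(k)) {
    seg <- x[(bounds[cls] + 1L):bounds[cls + 1L]]
    ssd <- ssd + sum((seg - mean(seg))^2)
  }
  attr(breaks, "ssd") <- ssd
  breaks
}

#' Assign level labels from natural breaks
#'
#' Maps scores to the five ordered levels \code{low < lower < medium <
#' higher < high} (or the first \code{k} of a generic ordering when
#' \code{k != 5}). Ties at a break go to the lower class.
#'
#' @param values Numeric scores.
#' @param breaks Breaks from [jenks_breaks()] (length \code{k - 1}).
#' @return Ordered factor of levels, lowest first.
#' @export
classify_levels <- function(values, breaks) {
  k <- length(breaks) + 1L
  labels <- if (k == 5L) c("low", "lower", "medium", "higher", "high")
            else paste0("class", seq_len(k))
  idx <- 1L + vapply(values, function(v) sum(v > breaks), integer(1))
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Classify provinces into QoL levels and account for grade transitions
#'
#' Applies five-class natural-breaks classification to the overall index,
#' computes class shares (counts over the 31-province roster, reported to
#' one decimal percent), and enumerates up/down/stable transitions between
#' consecutive waves, flagging "leap" moves of two or more classes.
#'
#' @param scores A \code{qol_scores} object (needs \code{province},
#'   \code{year} and the score column).
#' @param k Number of classes (default 5).
#' @param per_year If \code{TRUE} (default) each wave is classified on its
#'   own breaks; if \code{FALSE} one set of breaks is fitted to the pooled
#'   scores.
#' @param column Score column to classify (default \code{"A"}).
#' @return List of class \code{"level_classification"} with elements
#'   \code{classification} (province, year, level, class index),
#'   \code{breaks} (per-pool break values), \code{shares} (per year and
#'   level: count and one-decimal percent share), and \code{transitions}
#'   (province, period, from/to level, direction, leap).
#' @export
classify_and_transition <- function(scores, k = 5L, per_year = TRUE,
                                    column = "A") {
  years <- sort(unique(scores$year))
  cls <- scores[c("province", "year")]
  cls$score <- scores[[column]]
  breaks_list <- list()
  if (per_year) {
    cls$class_idx <- NA_integer_
    for (yr in years) {
      sel <- cls$year == yr
      br <- jenks_breaks(cls$score[sel], k)
      breaks_list[[as.character(yr)]] <- br
      cls$class_idx[sel] <- as.integer(classify_levels(cls$score[sel], br))
    }
    lv <- levels(classify_levels(cls$score[cls$year == years[1L]],
                                 breaks_list[[1L]]))
  } else {
    br <- jenks_breaks(cls$score, k)
    breaks_list[["pooled"]] <- br
    lev <- classify_levels(cls$score, br)
    cls$class_idx <- as.integer(lev)
    lv <- levels(lev)
  }
  cls$level <- factor(lv[cls$class_idx], levels = lv, ordered = TRUE)

  shares <- do.call(rbind, lapply(years, function(yr) {
    sub <- cls[cls$year == yr, ]
    cnt <- table(sub$level)
    data.frame(year = yr, level = names(cnt), count = as.integer(cnt),
               share_pct = round(100 * as.integer(cnt) / nrow(sub), 1),
               stringsAsFactors = FALSE)
  }))

  transitions <- NULL
  if (length(years) > 1L) {
    trans <- list()
    for (i in seq_len(length(years) - 1L)) {
      y0 <- years[i]; y1 <- years[i + 1L]
      a <- cls[cls$year == y0, c("province", "class_idx", "level")]
      b <- cls[cls$year == y1, c("province", "class_idx", "level")]
      m <- merge(a, b, by = "province", suffixes = c("_from", "_to"))
      delta <- m$class_idx_to - m$class_idx_from
      trans[[i]] <- data.frame(
        province = m$province,
        period = paste0(y0, "-", y1),
        from = as.character(m$level_from), to = as.character(m$level_to),
        direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down",
                                                   "stable")),
        leap = abs(delta) >= 2L,
        stringsAsFactors = FALSE)
    }
    transitions <- do.call(rbind, trans)
  }
  out <- list(classification = cls, breaks = breaks_list, shares = shares,
              transitions = transitions)
  class(out) <- "level_classification"
  out
}

#' @export
print.level_classification <- function(x, ...) {
  cat("Natural-breaks level classification (",
      length(x$breaks[[1L]]) + 1L, " classes)\n", sep = "")
  cat("Class shares by year (% of provinces):\n")
  print.data.frame(x$shares, row.names = FALSE)
  if (!is.null(x$transitions)) {
    for (p in unique(x$transitions$period)) {
      t <- x$transitions[x$transitions$period == p, ]
      cat(sprintf("%s: %d up (%s%%), %d down (%s%%), %d stable; %d leap\n",
                  p, sum(t$direction == "up"),
                  format(round(100 * mean(t$direction == "up"), 1)),
                  sum(t$direction == "down"),
                  format(round(100 * mean(t$direction == "down"), 1)),
                  sum(t$direction == "stable"), sum(t$leap)))
    }
  }
  invisible(x)
}

#' Share of provinces in the top classes
#'
#' Count-over-roster arithmetic for "medium and high" style statements:
#' the share of the 31 provinces whose level is at or above a floor class,
#' reported to one decimal percent.
#'
#' @param counts Integer count of provinces in the group of interest.
#' @param total Roster size (default 31).
#' @return Percent to one decimal.
#' @export
#' @examples
#' class_share(18)  # 58.1
class_share <- function(counts, total = 31L) {
  round(100 * counts / total, 1)
}
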