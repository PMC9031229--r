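#' Define an abridged mortality schedule
#'
#' An abridged mortality schedule is the input to the current (period)
#' life table: contiguous, ascending age intervals \code{[x, x+n)} closing
#' with a single open interval \code{[x, Inf)}, each carrying a central
#' death rate \code{m} (deaths per person-year of exposure).
#'
#' @param age_start Numeric vector of interval start ages, ascending,
#'   starting at 0.
#' @param width Interval widths in years; the last entry must be
#'   \code{Inf} (the open interval).
#' @param m Central death rates, all \code{>= 0}; the open-interval rate
#'   must be strictly positive (otherwise the tail holds infinite
#'   person-years).
#' @return data.frame of class \code{"mortality_schedule"}.
#' @seealso [life_table()]
#' @export
#' @examples
#' mortality_schedule(c(0, 5), c(5, Inf), c(0.001, 0.1))
mortality_schedule <- function(age_start, width, m) {
  if (length(age_start) != length(width) || length(width) != length(m))
    stop("age_start, width and m must have equal length")
  if (length(m) < 1L) stop("schedule must have at least one interval")
  if (any(m < 0)) stop("negative central death rate")
  if (!is.infinite(width[length(width)]))
    stop("last interval must be open (width = Inf)")
  if (any(is.infinite(width[-length(width)])))
    stop("only the last interval may be open")
  if (m[length(m)] <= 0)
    stop("open-interval death rate must be > 0 (finite tail person-years)")
  ends <- age_start + width
  if (length(age_start) > 1L) {
    if (any(diff(age_start) <= 0)) stop("age intervals must be ascending")
    if (any(abs(ends[-length(ends)] - age_start[-1L]) > 1e-9))
      stop("age intervals must be contiguous")
  }
  if (age_start[1L] != 0) stop("schedule must start at age 0")
  out <- data.frame(age_start = age_start, width = width, m = m)
  class(out) <- c("mortality_schedule", "data.frame")
  out
}

#' Construct a current (period) abridged life table
#'
#' Follows a synthetic cohort of \code{radix} simultaneous births through
#' the period's age-specific central death rates \code{m}, producing the
#' classical columns: death probability \code{q}, survivors \code{l},
#' deaths \code{d}, person-years lived \code{L}, person-years remaining
#' \code{T} and remaining life expectancy \code{e}.
#'
#' For a closed interval of width \code{n} with separation factor \code{a}
#' (average years lived in the interval by those dying in it):
#' \deqn{q = n m / (1 + (n - a) m), \quad L = n\,l_{x+n} + a\,d.}
#' \code{q} is capped at 1 (with a warning) on extreme rates. The open
#' interval uses \code{q = 1} and \code{L = l / m}. \code{T} is the
#' reverse cumulative sum of \code{L} and \code{e = T / l} wherever
#' \code{l > 0}.
#'
#' Separation factors default to the interval midpoint \code{a = n/2}. The
#' \code{"infant"} convention additionally replaces \code{a} in a leading
#' one-year interval by \code{0.1 + 2.5 m0}, bounded to \code{[0.01,
#' 0.35]}, reflecting the concentration of infant deaths early in the
#' first year of life.
#'
#' @param schedule A [mortality_schedule()].
#' @param a_convention \code{"midpoint"} (default) or \code{"infant"}.
#' @param radix Size of the synthetic birth cohort (default 100,000).
#' @return data.frame of class \code{"life_table"} with columns
#'   \code{age_start}, \code{width}, \code{m}, \code{a}, \code{q},
#'   \code{l}, \code{d}, \code{L}, \code{T}, \code{e}.
#' @export
#' @examples
#' sched <- mortality_schedule(c(0, 5), c(5, Inf), c(0, 0.1))
#' life_table(sched)   # e0 = 5 + 1/0.1 = 15 years
life_table <- function(schedule, a_convention = c("midpoint", "infant"),
                       radix = 1e5) {
  a_convention <- match.arg(a_convention)
  if (!inherits(schedule, "mortality_schedule"))
    schedule <- mortality_schedule(schedule$age_start, schedule$width,
                                   schedule$m)
  if (radix <= 0) stop("radix must be positive")
  n <- schedule$width
  m <- schedule$m
  k <- length(m)
  a <- n / 2
  if (a_convention == "infant" && k > 1L && n[1L] == 1) {
    a[1L] <- min(max(0.1 + 2.5 * m[1L], 0.01), 0.35)
  }

  q <- numeric(k)
  closed <- seq_len(k - 1L)
  q[closed] <- n[closed] * m[closed] / (1 + (n[closed] - a[closed]) * m[closed])
  if (any(q[closed] > 1)) {
    warning("death probability capped at 1 for ", sum(q[closed] > 1),
            " interval(s) with extreme rates")
    q[closed] <- pmin(q[closed], 1)
  }
  q[k] <- 1

  l <- numeric(k)
  l[1L] <- radix
  if (k > 1L) for (i in closed) l[i + 1L] <- l[i] * (1 - q[i])
  d <- l * q
  L <- numeric(k)
  if (k > 1L) L[closed] <- n[closed] * (l[closed] - d[closed]) +
      a[closed] * d[closed]
  L[k] <- l[k] / m[k]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  out <- data.frame(age_start = schedule$age_start, width = n, m = m, a = a,
                    q = q, l = l, d = d, L = L, T = Tx, e = e)
  attr(out, "radix") <- radix
  attr(out, "a_convention") <- a_convention
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life expectancy at birth from a mortality schedule
#'
#' Convenience wrapper returning \code{e} at the first age group of
#' [life_table()]; this is the average-life-expectancy (\code{ALE})
#' indicator of the health dimension.
#'
#' @inheritParams life_table
#' @return Life expectancy at age 0, in years.
#' @export
life_expectancy_at_birth <- function(schedule,
                                     a_convention = c("midpoint", "infant"),
                                     radix = 1e5) {
  lt <- life_table(schedule, a_convention = a_convention, radix = radix)
  lt$e[1L]
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Abridged period life table (radix ", format(attr(x, "radix")),
      ", separation factors: ", attr(x, "a_convention"), ")\n", sep = "")
  cat("Life expectancy at birth:", format(round(x$e[1L], 2), nsmall = 2),
      "years\n")
  print.data.frame(as.data.frame(lapply(x, function(col)
    if (is.numeric(col)) signif(col, digits) else col)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.life_table <- function(object, ...) {
  res <- list(
    e0 = object$e[1L],
    radix = attr(object, "radix"),
    n_groups = nrow(object),
    total_deaths = sum(object$d),
    median_age_at_death = {
      half <- attr(object, "radix") / 2
      i <- which(object$l <= half)[1L]
      if (is.na(i)) NA_real_ else object$age_start[i]
    }
  )
  class(res) <- "summary.life_table"
  res
}

#' @export
print.summary.life_table <- function(x, ...) {
  cat("Life table:", x$n_groups, "age groups, radix", format(x$radix), "\n")
  cat("  e0:", round(x$e0, 3), "years\n")
  cat("  total deaths:", format(x$total_deaths), "(= radix)\n")
  if (!is.na(x$median_age_at_death))
    cat("  survivors fall below radix/2 at age",
        x$median_age_at_death, "\n")
  invisible(x)
}

#' Read/write mortality schedules as delimited text
#'
#' Schedules are stored with columns \code{age_start},
#' \code{age_width_or_open} (a number, or the token \code{open} for the
#' final interval) and \code{m}.
#'
#' @param path File path.
#' @return For the reader, a [mortality_schedule()].
#' @export
read_mortality_schedule <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  width <- ifelse(tab$age_width_or_open %in% c("open", "Inf"),
                  Inf, suppressWarnings(as.numeric(tab$age_width_or_open)))
  mortality_schedule(as.numeric(tab$age_start), width, as.numeric(tab$m))
}

#' @rdname read_mortality_schedule
#' @param schedule A [mortality_schedule()] to write.
#' @export
write_mortality_schedule <- function(schedule, path) {
  tab <- data.frame(age_start = schedule$age_start,
                    age_width_or_open = ifelse(is.infinite(schedule$width),
                                               "open", schedule$width),
                    m = schedule$m)
  write_panel(tab, path)
}

#' Standard census abridged age ladder
#'
#' The default age grouping 0-1, 1-4, then 5-year groups up to the open
#' interval starting at \code{open_age}.
#'
#' @param open_age Start of the open interval (default 85).
#' @return data.frame with columns \code{age_start} and \code{width}.
#' @export
abridged_age_ladder <- function(open_age = 85) {
  starts <- c(0, 1, seq(5, open_age, by = 5))
  widths <- c(diff(starts), Inf)
  data.frame(age_start = starts, width = widths)
}
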