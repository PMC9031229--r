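#' Construct and validate a province-year panel
#'
#' A province-year panel is a long-format table of observed indicator or
#' covariate values keyed by \code{(province, year, code)}. Validation
#' enforces the fixed 31-unit provincial roster, known codes from the
#' supplied registry, uniqueness of the key and finiteness of every value.
#'
#' @param records data.frame with columns \code{province}, \code{year},
#'   \code{code}, \code{value}.
#' @param registry Registry data.frame with a \code{code} column
#'   ([indicator_registry()] or [covariate_registry()]), or \code{NULL} to
#'   skip code checking.
#' @return The validated data.frame with class \code{"qol_panel"}.
#' @export
as_panel <- function(records, registry = NULL) {
  needed <- c("province", "year", "code", "value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L)
    stop("panel is missing columns: ", paste(missing, collapse = ", "))
  records <- as.data.frame(records)[needed]
  records$province <- as.character(records$province)
  records$year <- as.integer(records$year)
  records$code <- as.character(records$code)
  records$value <- as.numeric(records$value)

  roster <- province_roster()
  unknown_prov <- setdiff(unique(records$province), roster)
  if (length(unknown_prov) > 0L)
    stop("unknown province(s): ", paste(unknown_prov, collapse = ", "),
         "; the roster is: ", paste(roster, collapse = ", "))
  if (!is.null(registry)) {
    unknown_code <- setdiff(unique(records$code), registry$code)
    if (length(unknown_code) > 0L)
      stop("unknown code(s): ", paste(unknown_code, collapse = ", "))
  }
  key <- paste(records$province, records$year, records$code, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L)
    stop("duplicate (province, year, code) key(s): ",
         paste(unique(dup), collapse = "; "))
  if (any(!is.finite(records$value)))
    stop("non-finite value(s) in panel")
  rownames(records) <- NULL
  class(records) <- c("qol_panel", "data.frame")
  records
}

#' Read a province-year panel from a delimited text file
#'
#' Accepts either long format (columns \code{province}, \code{year},
#' \code{code}, \code{value}) or wide format (columns \code{province},
#' \code{year} plus one column per code), auto-detected from the header.
#' Lines starting with \code{#} (provenance headers written by
#' [write_panel()]) are skipped.
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @inheritParams as_panel
#' @return A validated \code{qol_panel}.
#' @export
load_panel <- function(path, registry = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  cols <- names(tab)
  if (all(c("province", "year", "code", "value") %in% cols)) {
    return(as_panel(tab, registry))
  }
  if (!all(c("province", "year") %in% cols))
    stop("file must have columns (province, year, code, value) or ",
         "(province, year, <one column per code>)")
  codes <- setdiff(cols, c("province", "year"))
  long <- data.frame(
    province = rep(tab$province, times = length(codes)),
    year = rep(tab$year, times = length(codes)),
    code = rep(codes, each = nrow(tab)),
    value = unlist(tab[codes], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  as_panel(long, registry)
}

#' Write a panel (or any table) as delimited text with a provenance header
#'
#' All writers in the package emit a single \code{#}-prefixed provenance
#' line (tool version, seed if supplied, timestamp) followed by a standard
#' CSV with header row. [load_panel()] and plain
#' \code{read.csv(comment.char = "#")} both skip the provenance line.
#'
#' @param x data.frame to write.
#' @param path Output file path.
#' @param seed Optional integer recorded in the provenance line.
#' @return Invisibly, \code{path}.
#' @export
write_panel <- function(x, path, seed = NULL) {
  header <- sprintf("# qolindex %s | seed: %s | written: %s",
                    as.character(utils::packageVersion("qolindex")),
                    if (is.null(seed)) "NA" else format(seed),
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Reshape a long panel into an observation-by-code value matrix
#'
#' Produces the raw value matrix consumed by the standardization stage:
#' rows are \code{(province, year)} observations in the requested order,
#' columns are codes in the requested order. Every requested cell must be
#' present in the panel.
#'
#' @param panel A \code{qol_panel}.
#' @param codes Ordered character vector of codes (columns).
#' @param observations Ordered data.frame with columns \code{province} and
#'   \code{year} (rows). Defaults to all observations present, ordered by
#'   year then roster position.
#' @return Numeric matrix with rownames \code{"province|year"} and
#'   colnames \code{codes}.
#' @export
panel_to_matrix <- function(panel, codes = sort(unique(panel$code)),
                            observations = NULL) {
  if (is.null(observations)) {
    obs <- unique(panel[c("province", "year")])
    obs <- obs[order(obs$year, match(obs$province, province_roster())), ]
    observations <- obs
  }
  obs_key <- paste(observations$province, observations$year, sep = "|")
  mat <- matrix(NA_real_, nrow = nrow(observations), ncol = length(codes),
                dimnames = list(obs_key, codes))
  cell <- paste(panel$province, panel$year, sep = "|")
  for (j in seq_along(codes)) {
    rows <- panel$code == codes[j]
    idx <- match(obs_key, cell[rows])
    mat[, j] <- panel$value[rows][idx]
  }
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    first <- miss[1L, ]
    stop("missing cell(s): ", nrow(miss), " requested cells absent, e.g. ",
         "observation '", obs_key[first[1L]], "', code '",
         codes[first[2L]], "'")
  }
  mat
}

#' Reshape an observation-by-code matrix back into a long panel
#'
#' Inverse of [panel_to_matrix()]; rownames must be
#' \code{"province|year"} keys.
#'
#' @param mat Numeric matrix with \code{"province|year"} rownames and code
#'   colnames.
#' @return A \code{qol_panel}.
#' @export
matrix_to_panel <- function(mat) {
  parts <- strsplit(rownames(mat), "|", fixed = TRUE)
  prov <- vapply(parts, `[`, character(1), 1L)
  year <- as.integer(vapply(parts, `[`, character(1), 2L))
  as_panel(data.frame(
    province = rep(prov, times = ncol(mat)),
    year = rep(year, times = ncol(mat)),
    code = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat),
    stringsAsFactors = FALSE
  ))
}

#' Completeness mask of a panel
#'
#' For each (year, code) pair, reports how many of the 31 provinces have a
#' value, supporting the completeness requirement of the index stage.
#'
#' @param panel A \code{qol_panel}.
#' @return data.frame with columns \code{year}, \code{code},
#'   \code{n_present}, \code{complete} (logical, all 31 present).
#' @export
completeness_mask <- function(panel) {
  agg <- stats::aggregate(list(n_present = panel$value),
                          by = list(year = panel$year, code = panel$code),
                          FUN = length)
  agg$complete <- agg$n_present == length(province_roster())
  agg[order(agg$year, agg$code), ]
}

#' Fill missing cells from the nearest available wave
#'
#' The index stage requires complete cells. Rather than filling silently,
#' this utility imputes each missing \code{(province, year, code)} cell by
#' carrying the value from the nearest wave (earlier wave wins ties) in
#' which that province-code cell is observed, and reports every imputation
#' both as a message and in the returned log.
#'
#' @param panel A \code{qol_panel}, possibly incomplete.
#' @param provinces,years,codes The full grid that should be present;
#'   defaults to the roster crossed with the years and codes found in the
#'   panel.
#' @param quiet Suppress per-imputation messages.
#' @return The completed \code{qol_panel}, with attribute
#'   \code{"imputation_log"}: a data.frame of (province, year, code,
#'   source_year, value) rows, one per filled cell.
#' @export
fill_nearest_wave <- function(panel, provinces = province_roster(),
                              years = sort(unique(panel$year)),
                              codes = sort(unique(panel$code)),
                              quiet = FALSE) {
  grid <- expand.grid(province = provinces, year = years, code = codes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(p, y, co) paste(p, y, co, sep = "|")
  have <- key(panel$province, panel$year, panel$code)
  idx <- match(key(grid$province, grid$year, grid$code), have)
  grid$value <- panel$value[idx]
  log <- data.frame(province = character(), year = integer(),
                    code = character(), source_year = integer(),
                    value = numeric(), stringsAsFactors = FALSE)
  miss <- which(is.na(grid$value))
  for (i in miss) {
    cand <- panel[panel$province == grid$province[i] &
                    panel$code == grid$code[i], ]
    if (nrow(cand) == 0L)
      stop("cannot impute: no wave observes (", grid$province[i], ", ",
           grid$code[i], ")")
    dist <- abs(cand$year - grid$year[i])
    pick <- cand[order(dist, cand$year), ][1L, ]
    grid$value[i] <- pick$value
    log <- rbind(log, data.frame(province = grid$province[i],
                                 year = grid$year[i], code = grid$code[i],
                                 source_year = pick$year, value = pick$value,
                                 stringsAsFactors = FALSE))
    if (!quiet)
      message("imputed (", grid$province[i], ", ", grid$year[i], ", ",
              grid$code[i], ") from wave ", pick$year)
  }
  out <- as_panel(grid)
  attr(out, "imputation_log") <- log
  out
}

#' @export
print.qol_panel <- function(x, ...) {
  cat("Province-year panel:", nrow(x), "records |",
      length(unique(x$province)), "provinces x",
      length(unique(x$year)), "waves x",
      length(unique(x$code)), "codes\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more records\n")
  invisible(x)
}
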