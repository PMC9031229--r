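#' Indicator registry for the oldest-old quality-of-life index
#'
#' Returns the registry of the 16 indicators making up the three-dimension
#' (health, participation, security) evaluation system for the quality of
#' life of the oldest-old. Each entry carries the short code used in panel
#' files, a human-readable name, the criterion-layer dimension it belongs
#' to, its polarity (whether larger raw values mean better quality of
#' life), and its units.
#'
#' The disability rate (\code{DR}) is the only negative-polarity
#' (cost-type) indicator; all others are benefit-type. The published index
#' system's prose announces six health indicators but names only five;
#' the registry implements the five named ones (\code{ALE}, \code{DR},
#' \code{SR}, \code{UBMI}, \code{PMHT}).
#'
#' Units are carried verbatim as free text: several per-1000 counts are
#' labelled "%" in the source system and are not reinterpreted.
#'
#' @return A data.frame with columns \code{code}, \code{name},
#'   \code{dimension}, \code{polarity}, \code{units}; 16 rows.
#' @seealso [covariate_registry()], [region_scheme()]
#' @export
#' @examples
#' reg <- indicator_registry()
#' table(reg$dimension)
indicator_registry <- function() {
  reg <- data.frame(
    code = c("ALE", "DR", "SR", "UBMI", "PMHT",
             "AYE", "SAC", "OAO", "OAA", "OAS",
             "OSC", "PCR", "UBPI", "BOC", "BPB", "SPP"),
    name = c(
      "Average life expectancy",
      "Disability rate of older adults",
      "Spouse rate of older adults",
      "Urban employee basic medical insurance participation rate",
      "Medical and health technical personnel per 100 oldest-old",
      "Average years of education of older adults",
      "Old-age activity centers per 1000 older adults",
      "Old-age organizations per 1000 older adults",
      "Geriatric associations per 10,000 older adults",
      "Old-age school enrollment rate of older adults",
      "Old-age subsidy coverage rate",
      "Coverage rate of older adults' retirement pension",
      "Urban pension insurance participation rate",
      "Old-age service beds per 1000 older adults",
      "Urban employees' basic pension insurance benefits",
      "Socialized pension payment rate"),
    dimension = rep(c("health", "participation", "security"), c(5L, 5L, 6L)),
    polarity = "positive",
    units = c("year", "%", "%", "%", "people",
              "year", "%", "%", "number", "%",
              "%", "%", "%", "number", "10,000 RMB", "%"),
    stringsAsFactors = FALSE
  )
  reg$polarity[reg$code == "DR"] <- "negative"
  reg
}

#' Covariate registry for the panel regression stage
#'
#' The nine province-level regressors used to explain regional differences
#' in the composite quality-of-life index, with the sign each is
#' hypothesized to carry and any transform applied. \code{lnGDP} is the
#' natural log of per-capita GDP; all other covariates enter untransformed.
#' \code{AYE} (average years of education) doubles as indicator C6 of the
#' participation dimension; it is defined once here and referenced by code
#' from both registries.
#'
#' @return A data.frame with columns \code{code}, \code{name},
#'   \code{hypothesized_sign}, \code{transform}; 9 rows.
#' @export
covariate_registry <- function() {
  data.frame(
    code = c("POO", "ODR", "AHS", "lnGDP", "PST", "UL", "UR", "AYE", "SAE"),
    name = c(
      "Proportion of the oldest-old among older adults",
      "Old-age dependency ratio",
      "Average household size",
      "Log per-capita gross domestic product",
      "Secondary and tertiary industry share of GDP",
      "Urbanization level",
      "Unemployment rate",
      "Per-capita years of education",
      "Per-capita social assistance expenditure"),
    hypothesized_sign = c("+", "+", "-", "+", "+", "+", "+", "+", "+"),
    transform = c("none", "none", "none", "natural-log", "none", "none",
                  "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Provincial roster of the 31 mainland evaluation units
#'
#' The fixed roster of 31 provinces, municipalities and autonomous regions
#' of mainland China used as evaluation units (Taiwan, Hong Kong and Macao
#' excluded).
#'
#' @return Character vector of 31 province names.
#' @export
province_roster <- function() {
  c("Beijing", "Tianjin", "Hebei", "Shanxi", "Inner Mongolia",
    "Liaoning", "Jilin", "Heilongjiang",
    "Shanghai", "Jiangsu", "Zhejiang", "Anhui", "Fujian", "Jiangxi",
    "Shandong", "Henan", "Hubei", "Hunan", "Guangdong", "Guangxi",
    "Hainan", "Chongqing", "Sichuan", "Guizhou", "Yunnan", "Tibet",
    "Shaanxi", "Gansu", "Qinghai", "Ningxia", "Xinjiang")
}

#' Four-region scheme for regional aggregation
#'
#' Maps each of the 31 provincial units to one of the four macro-regions
#' (east, central, west, northeast) of the national statistical standard:
#' 10 eastern, 6 central, 12 western and 3 northeastern units. The scheme
#' can be overridden by supplying a YAML file mapping province names to
#' regions, so alternative partitions can be analyzed without code change.
#'
#' @param path Optional path to a YAML file of \code{province: region}
#'   pairs covering all 31 units.
#' @return Named character vector: names are provinces, values are one of
#'   \code{"east"}, \code{"central"}, \code{"west"}, \code{"northeast"}.
#' @export
#' @examples
#' table(region_scheme())
region_scheme <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    scheme <- vapply(raw, as.character, character(1))
    validate_region_scheme(scheme)
    return(scheme)
  }
  east <- c("Beijing", "Tianjin", "Hebei", "Shanghai", "Jiangsu",
            "Zhejiang", "Fujian", "Shandong", "Guangdong", "Hainan")
  central <- c("Shanxi", "Anhui", "Jiangxi", "Henan", "Hubei", "Hunan")
  west <- c("Inner Mongolia", "Guangxi", "Chongqing", "Sichuan", "Guizhou",
            "Yunnan", "Tibet", "Shaanxi", "Gansu", "Qinghai", "Ningxia",
            "Xinjiang")
  northeast <- c("Liaoning", "Jilin", "Heilongjiang")
  scheme <- c(stats::setNames(rep("east", length(east)), east),
              stats::setNames(rep("central", length(central)), central),
              stats::setNames(rep("west", length(west)), west),
              stats::setNames(rep("northeast", length(northeast)), northeast))
  scheme[province_roster()]
}

validate_region_scheme <- function(scheme) {
  roster <- province_roster()
  missing <- setdiff(roster, names(scheme))
  if (length(missing) > 0L)
    stop("region scheme missing provinces: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(scheme), roster)
  if (length(extra) > 0L)
    stop("region scheme has unknown provinces: ", paste(extra, collapse = ", "))
  bad <- setdiff(unique(scheme), c("east", "central", "west", "northeast"))
  if (length(bad) > 0L)
    stop("unknown regions: ", paste(bad, collapse = ", "))
  invisible(scheme)
}
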