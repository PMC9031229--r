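#' Published reference averages of the oldest-old QoL index
#'
#' Loads the published national and regional averages (plus national
#' maximum and minimum with province labels) of the overall
#' quality-of-life index for the oldest-old at the three study waves
#' (2005, 2010, 2015). These printed values are the input to the
#' percent-change arithmetic checks: for example, the national average
#' rose from 0.5595 to 0.5833, a 4.25\% increase.
#'
#' @return data.frame with columns \code{year}, \code{national},
#'   \code{maximum}, \code{maximum_province}, \code{minimum},
#'   \code{minimum_province}, \code{east}, \code{central}, \code{west},
#'   \code{northeast}.
#' @export
#' @examples
#' ref <- reference_index_averages()
#' percent_change(ref$national[1], ref$national[3])  # 4.25
reference_index_averages <- function() {
  path <- system.file("extdata", "reference_index_averages.csv",
                      package = "qolindex", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
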