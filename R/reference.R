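#' Published milestone reference values for the clinical cohort
#'
#' Group means and standard deviations of the twelve perfusion milestone
#' features reported for the motivating clinical cohort (24 colorectal
#' liver metastasis ROI groups vs 24 healthy liver ROI groups), together
#' with the printed Mann-Whitney significance call per row. These values
#' parameterize the synthetic-angiogram generator ([kineticDefaults()])
#' and serve as worked-example inputs.
#'
#' Units: \code{tmax}, \code{tHalf}-derived ratio and \code{com} in
#' seconds; \code{fmax}, \code{fEnd}, \code{delta10} in greyscale units;
#' slopes in g.u./s; \code{upslope} in g.u./s; moments unitless.
#'
#' @return data.frame with columns \code{feature}, \code{crlmMean},
#'   \code{crlmSD}, \code{healthyMean}, \code{healthySD}, \code{pPrinted},
#'   \code{significant}, one row per feature in the canonical order of
#'   [featureNames()].
#' @examples
#' ref <- referenceMilestones()
#' # outflow slope over 10 s is the 10-s intensity change divided by 10
#' ref$crlmMean[ref$feature == "delta10"] / 10
#' @export
referenceMilestones <- function() {
  data.frame(
    feature = c("tmax", "fmax", "fEnd", "upslope", "timeRatio", "delta10",
                "slope10", "slope20", "slope60", "kurtosis", "skew", "com"),
    crlmMean = c(23.931, 123.594, 102.861, 6.951, 0.341, -24.471,
                 -2.447, -1.190, -0.283, 2.053, -1.399, 49.536),
    crlmSD = c(13.370, 51.253, 48.899, 4.458, 0.208, 13.700,
               1.370, 0.727, 0.326, 2.037, 0.966, 6.504),
    healthyMean = c(82.616, 195.322, 188.988, 2.660, 0.127, 36.726,
                    3.672, 0.831, 0.673, 1.366, -1.495, 53.995),
    healthySD = c(12.888, 57.883, 57.948, 1.446, 0.076, 30.341,
                  3.034, 0.837, 0.488, 2.164, 0.589, 3.262),
    pPrinted = c("<0.001", "<0.001", "<0.001", "<0.001", "<0.001", "<0.001",
                 "<0.001", "<0.001", "<0.001", "0.022", "0.572", "<0.001"),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
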