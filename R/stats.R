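#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with elements \code{W} and \code{p}.
#' @export
normalityTest <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    .stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (length(unique(values)) == 1L)
    .stopf("constant sample: normality test undefined")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Wraps the two-sided Mann-Whitney (Wilcoxon rank-sum) test: the exact
#' p-value for small samples without ties, the normal approximation with
#' tie correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list with elements \code{U} (the U statistic of the first
#'   sample) and \code{p}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
compareGroups <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Group milestone summary table
#'
#' Per-feature group means and standard deviations (sample SD) with a
#' two-sided Mann-Whitney comparison of the two groups and a
#' significance star at p < 0.05 (raw p-values, no multiplicity
#' correction, mirroring the cohort report format). Rows follow the
#' canonical milestone order. Features entirely missing in a group are
#' flagged and get no p-value.
#'
#' @param featureTable feature table (see [computeFeatureTable()]).
#' @param groups the two labels compared (default CRLM vs healthy).
#' @param alpha significance level for the star (default 0.05).
#' @return data.frame with one row per feature: means, SDs, \code{U},
#'   \code{p}, \code{significant}, \code{flagged}.
#' @export
buildMilestoneTable <- function(featureTable, groups = c("crlm", "healthy"),
                                alpha = 0.05) {
  .checkFeatureTable(featureTable)
  present <- intersect(groups, unique(featureTable$label))
  if (length(present) < 2L)
    .stopf("both groups must be present in the feature table")
  a <- featureTable[featureTable$label == groups[1], , drop = FALSE]
  b <- featureTable[featureTable$label == groups[2], , drop = FALSE]
  rows <- lapply(featureNames(), function(f) {
    va <- a[[f]][!is.na(a[[f]])]
    vb <- b[[f]][!is.na(b[[f]])]
    flagged <- !length(va) || !length(vb)
    if (flagged) {
      U <- NA_real_; p <- NA_real_
    } else {
      cmpr <- compareGroups(va, vb)
      U <- cmpr$U; p <- cmpr$p
    }
    data.frame(feature = f,
               mean1 = if (length(va)) mean(va) else NA_real_,
               sd1 = if (length(va) > 1) sd(va) else NA_real_,
               mean2 = if (length(vb)) mean(vb) else NA_real_,
               sd2 = if (length(vb) > 1) sd(vb) else NA_real_,
               U = U, p = p,
               significant = !is.na(p) && p < alpha,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0(groups[1], c("Mean", "SD")),
                       paste0(groups[2], c("Mean", "SD")))
  rownames(out) <- NULL
  out
}

#' Signal-per-area quantification of a microscopy section
#'
#' Mean fluorescence signal per unit area for the lesion and healthy
#' regions of a section, with the healthy/lesion contrast ratio. A
#' zero-signal lesion yields an infinite ratio, which is flagged rather
#' than silently propagated.
#'
#' @param section a \linkS4class{SectionImage}.
#' @return list with \code{perRegion} (data.frame: region, area,
#'   signalPerArea), \code{contrastRatio} and \code{flagged}.
#' @export
sectionSignalPerArea <- function(section) {
  masks <- section@masks[c("lesion", "healthy")]
  areas <- vapply(masks, sum, numeric(1))
  if (any(areas == 0)) .stopf("empty region mask")
  if (any(masks$lesion & masks$healthy)) .stopf("region masks must be disjoint")
  spa <- vapply(names(masks), function(nm)
    sum(section@intensity[masks[[nm]]]) / areas[[nm]], numeric(1))
  ratio <- spa[["healthy"]] / spa[["lesion"]]
  flagged <- !is.finite(ratio)
  if (flagged)
    warning("lesion region has zero signal; contrast ratio is infinite")
  list(perRegion = data.frame(region = names(masks), area = unname(areas),
                              signalPerArea = unname(spa),
                              stringsAsFactors = FALSE),
       contrastRatio = ratio, flagged = flagged)
}

#' Staining attenuation ratio
#'
#' Ratio of mean fluorescence signal between matched unstained and
#' stained sections over the common tissue mask (H&E staining with
#' cover-slipping attenuates the ICG signal).
#'
#' @param unstained,stained \linkS4class{SectionImage}s with matched
#'   masks.
#' @param mask optional logical matrix; defaults to the whole tissue
#'   (lesion plus healthy).
#' @return unitless attenuation ratio (unstained / stained).
#' @export
attenuationRatio <- function(unstained, stained, mask = NULL) {
  if (!all(dim(unstained@intensity) == dim(stained@intensity)))
    .stopf("sections must have matched geometry")
  if (is.null(mask))
    mask <- unstained@masks$lesion | unstained@masks$healthy
  ms <- mean(stained@intensity[mask])
  if (ms <= 0) .stopf("stained section has zero mean signal")
  mean(unstained@intensity[mask]) / ms
}
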