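#' @include AllClasses.R
#' @importFrom rlang .data
NULL

#' Assemble per-slice records into a depth profile
#'
#' Attaches physical depths (`depthMm = depthIndex x sliceSpacingUm / 1000`)
#' and orders records by depth.  Records are stored unsmoothed; any
#' moving-average smoothing is applied at plotting time only.
#'
#' @param records data.frame of per-slice metrics with a `depthIndex`
#'   column (e.g. rows from [computeAllMetrics()], optionally merged with
#'   [computeMorpho()] columns).
#' @param sliceSpacingUm slice spacing in micrometers (isotropic scans: the
#'   pixel size).
#' @param specimenId specimen label.
#' @param group group label, e.g. `"CTRL"` or `"HOA"`.
#' @return a [DepthProfile-class].
#' @export
profileStack <- function(records, sliceSpacingUm = 20.5,
                         specimenId = "specimen", group = "CTRL") {
  if (!"depthIndex" %in% names(records))
    stop("records must contain a depthIndex column")
  if (anyDuplicated(records$depthIndex))
    stop("duplicate depth indices in records")
  records <- records[order(records$depthIndex), , drop = FALSE]
  records$depthMm <- records$depthIndex * sliceSpacingUm / 1000
  rownames(records) <- NULL
  new("DepthProfile", specimenId = specimenId, group = group,
      records = records)
}

#' Depth-region index ranges
#'
#' Splits `nSlices` depth indices into the proximal first half
#' `[0, floor(n/2))`, the distal second half `[floor(n/2), n)`, and the
#' whole range — the three volumes of interest used for region-wise group
#' comparisons.
#'
#' @param nSlices slice count (>= 2).
#' @return list of 0-based index vectors `first_half`, `second_half`,
#'   `whole`.
#' @export
regionSlices <- function(nSlices) {
  if (nSlices < 2) stop("need at least 2 slices to define regions")
  half <- floor(nSlices / 2)
  list(first_half = 0:(half - 1L),
       second_half = half:(nSlices - 1L),
       whole = 0:(nSlices - 1L))
}

#' Per-group mean curve and SD band over depth
#'
#' Resamples every profile's metric onto a common depth grid (the grid of
#' the shortest profile, by linear interpolation; exact on already-aligned
#' grids) and returns the across-specimen mean and sample SD per depth for
#' each group present.
#'
#' @param profiles list of [DepthProfile-class] objects.
#' @param metricName metric column to aggregate.
#' @return named list (one element per group) of data.frames with columns
#'   `depthMm`, `mean`, `sd`, `n`.
#' @export
groupBand <- function(profiles, metricName) {
  stopifnot(length(profiles) >= 1)
  sizes <- vapply(profiles, function(p) nrow(p@records), integer(1))
  grid <- profiles[[which.min(sizes)]]@records$depthMm
  groups <- vapply(profiles, function(p) p@group, "")
  out <- list()
  for (g in unique(groups)) {
    ps <- profiles[groups == g]
    ys <- vapply(ps, function(p) {
      r <- p@records
      if (length(r$depthMm) == 1) rep(r[[metricName]], length(grid))
      else approx(r$depthMm, r[[metricName]], xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    ys <- matrix(ys, nrow = length(grid))
    if (ncol(ys) == 1)
      warning("single specimen in group ", g, ": SD band is 0")
    out[[g]] <- data.frame(
      depthMm = grid,
      mean = rowMeans(ys),
      sd = if (ncol(ys) > 1) apply(ys, 1, sd) else rep(0, length(grid)),
      n = ncol(ys))
  }
  out
}

#' Unpaired two-group comparison of a region-mean metric
#'
#' The unit of analysis is the per-specimen mean of the metric over the
#' requested depth region (slices within a specimen are not independent, so
#' tests run on specimen-level summaries).  Shapiro-Wilk normality p-values
#' are reported per group, followed by an unpaired two-sample t test
#' (Student's pooled-variance by default, Welch with `welch = TRUE`),
#' significant at alpha = 0.05.
#'
#' @param profiles list of [DepthProfile-class] objects covering exactly two
#'   groups, >= 2 specimens per group.
#' @param metricName metric column to compare.
#' @param region `"whole"`, `"first_half"` or `"second_half"`.
#' @param welch use Welch's unequal-variance t test.
#' @return one-row data.frame: groups, per-group mean/SD/n/Shapiro-Wilk p,
#'   t statistic, degrees of freedom, p-value, significance flag.
#' @export
compareGroups <- function(profiles, metricName,
                          region = c("whole", "first_half", "second_half"),
                          welch = FALSE) {
  region <- match.arg(region)
  groups <- vapply(profiles, function(p) p@group, "")
  glev <- sort(unique(groups))
  if (length(glev) != 2) stop("need exactly two groups")
  regionMean <- function(p) {
    r <- p@records
    idx <- regionSlices(nrow(r))[[region]] + 1L   # positional, depth-ordered
    mean(r[[metricName]][idx], na.rm = TRUE)
  }
  x <- vapply(profiles[groups == glev[1]], regionMean, numeric(1))
  y <- vapply(profiles[groups == glev[2]], regionMean, numeric(1))
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 specimens per group")
  shap <- function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) return(NA_real_)
    shapiro.test(v)$p.value
  }
  tt <- tryCatch(t.test(x, y, var.equal = !welch), error = function(e) {
    if (!grepl("constant", conditionMessage(e))) stop(e)
    # degenerate: both groups (essentially) constant; identical means give
    # t = 0, p = 1, otherwise an infinite separation
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    list(statistic = c(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf),
         parameter = c(df = length(x) + length(y) - 2),
         p.value = if (eq) 1 else 0)
  })
  data.frame(
    metric = metricName, region = region,
    group1 = glev[1], n1 = length(x), mean1 = mean(x), sd1 = sd(x),
    shapiroP1 = shap(x),
    group2 = glev[2], n2 = length(y), mean2 = mean(y), sd2 = sd(y),
    shapiroP2 = shap(y),
    tStatistic = unname(tt$statistic), df = unname(tt$parameter),
    pValue = tt$p.value, significant = tt$p.value < 0.05,
    stringsAsFactors = FALSE)
}

#' Plot group mean curves with SD bands over depth
#'
#' One panel per metric: per-group mean (solid line) and +/- 1 SD shaded
#' band as a function of depth.  Optional moving-average smoothing is
#' applied to the displayed curves only.
#'
#' @param profiles list of [DepthProfile-class] objects.
#' @param metricNames metric columns to plot.
#' @param smoothWindow odd moving-average window (1 = none), plotting only.
#' @return a ggplot object.
#' @export
plotDepthBands <- function(profiles, metricNames = c("nVertices", "nEdges",
                                                     "nComponents"),
                           smoothWindow = 1L) {
  rows <- list()
  for (mn in metricNames) {
    bands <- groupBand(profiles, mn)
    for (g in names(bands)) {
      b <- bands[[g]]
      if (smoothWindow > 1) {
        b$mean <- movingAverage(b$mean, smoothWindow)
        b$sd <- movingAverage(b$sd, smoothWindow)
      }
      b$group <- g; b$metric <- mn
      rows[[length(rows) + 1L]] <- b
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depthMm, y = .data$mean,
                                   color = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "depth (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

movingAverage <- function(x, window) {
  k <- rep(1 / window, window)
  y <- as.numeric(stats::filter(x, k, sides = 2, circular = FALSE))
  y[is.na(y)] <- x[is.na(y)]
  y
}
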