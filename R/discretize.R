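#' Peak-based three-class cut points for a numeric lab variable
#'
#' Builds a histogram of the observed values and takes the two
#' highest-frequency local maxima as cut points (their bin centers, rounded to
#' one decimal). Rationale: interpreting a lab test depends on the range a
#' value falls in rather than its exact value, and cutting at the distribution
#' peaks keeps the three resulting categories usable for classification where
#' reference intervals would produce heavily unbalanced ones.
#'
#' Peaks are located on a lightly smoothed histogram (3-bin moving average)
#' whose bins are centered on the data range, and a second peak qualifies
#' only if it is non-adjacent to the first, reaches at least 20 percent of
#' its height, and is separated from it by a genuine valley (a bin at most
#' 90 percent of the smaller peak) — this keeps sampling noise on a smooth
#' unimodal distribution from masquerading as a second mode. Peaks whose
#' heights differ by no more than sampling noise are treated as tied and the
#' lower-valued ("first") peak is preferred. If any class would hold less
#' than 10 percent of the values the bins are widened (x1.5, up to three
#' retries); when no widening balances the classes the first usable scheme
#' is returned with a warning (genuinely spiky variables cannot always be
#' balanced).
#'
#' @param values observed numeric vector (at least 100 values).
#' @param binWidth histogram bin width; `NULL` uses Freedman-Diaconis with a
#'   floor of 0.01.
#' @param variable name stored in the scheme.
#' @return a \linkS4class{DiscretizationScheme}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 1, 0.05), rnorm(500, 2, 0.05))
#' cutpoints(peakCutpoints(x))
#' @export
peakCutpoints <- function(values, binWidth = NULL, variable = "variable") {
  values <- values[is.finite(values)]
  if (length(values) < 100)
    stop("peak-based discretization needs at least 100 observed values")
  h <- binWidth
  if (is.null(h)) {
    iqr <- stats::IQR(values)
    h <- max(2 * iqr / length(values)^(1 / 3), 0.01)
  }
  rng <- range(values)
  fallback <- NULL
  for (attempt in 0:3) {
    width <- h * 1.5^attempt
    breaks <- seq(rng[1] - width / 2, rng[2] + width, by = width)
    counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1L)
    centers <- breaks[-length(breaks)] + width / 2
    nb <- length(counts)
    if (nb < 3) next
    sm <- (c(0, counts[-nb]) + counts + c(counts[-1], 0)) / 3
    # plateau-safe local maxima on the smoothed counts: a run of equal
    # heights is one candidate, represented by its highest raw-count bin
    r <- rle(sm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    vals <- r$values
    peakRuns <- which(vals > c(-1, utils::head(vals, -1)) &
                        vals > c(utils::tail(vals, -1), -1))
    peaks <- vapply(peakRuns, function(k) {
      ix <- starts[k]:ends[k]
      ix[which.max(counts[ix])]
    }, integer(1))
    peaks <- peaks[counts[peaks] > 0]
    if (length(peaks) < 2) next
    # near-ties (within histogram sampling noise) prefer the lower peak
    tieTol <- 2 * sqrt(max(sm[peaks]))
    first <- min(peaks[sm[peaks] >= max(sm[peaks]) - tieTol])
    cand0 <- setdiff(peaks, first)
    ok <- vapply(cand0, function(cand) {
      if (abs(cand - first) <= 1) return(FALSE)
      if (sm[cand] < 0.2 * sm[first]) return(FALSE)
      # a genuine valley: raw counts between the peaks must dip more than
      # ~2 sd of counting noise below the smaller peak
      between <- seq(min(first, cand) + 1, max(first, cand) - 1)
      small <- min(counts[first], counts[cand])
      min(counts[between]) <= small - 2 * sqrt(small)
    }, logical(1))
    cand0 <- cand0[ok]
    if (!length(cand0)) next
    second <- min(cand0[sm[cand0] >= max(sm[cand0]) - tieTol])
    cp <- sort(round(centers[c(first, second)], 1))
    if (cp[1] >= cp[2]) next
    cls <- classifyAt(values, cp)
    scheme <- new("DiscretizationScheme", variable = variable,
                  cutpoints = cp, binWidth = width, histRange = rng,
                  classCounts = tabulate(cls, 3), method = "peaks")
    prop <- tabulate(cls, 3) / length(values)
    if (min(prop) >= 0.10) return(scheme)
    if (is.null(fallback)) fallback <- scheme
  }
  if (!is.null(fallback)) {
    warning("peak cut points for '", variable,
            "' leave a class below 10% of the values")
    return(fallback)
  }
  stop("no two usable peaks found for '", variable,
       "': distribution looks unimodal; consider quantileCutpoints()")
}

#' Tercile cut points (fallback for unimodal variables)
#'
#' The documented fallback when [peakCutpoints()] finds no second peak: cut at
#' the empirical terciles (rounded to one decimal), which guarantees
#' near-balanced classes.
#'
#' @inheritParams peakCutpoints
#' @return a \linkS4class{DiscretizationScheme} with `method = "quantile"`.
#' @export
quantileCutpoints <- function(values, variable = "variable") {
  values <- values[is.finite(values)]
  cp <- round(unname(stats::quantile(values, c(1 / 3, 2 / 3))), 1)
  if (cp[1] >= cp[2]) {
    # heavily discrete or narrow variable: nudge apart on the decimal grid
    cp <- c(cp[1], cp[1] + 0.1)
  }
  cls <- classifyAt(values, cp)
  new("DiscretizationScheme", variable = variable, cutpoints = cp,
      binWidth = NA_real_, histRange = range(values),
      classCounts = tabulate(cls, 3), method = "quantile")
}

# interval convention: [min, c1) -> 1, [c1, c2] -> 2, (c2, max] -> 3
classifyAt <- function(values, cp) {
  ifelse(values < cp[1], 1L, ifelse(values <= cp[2], 2L, 3L))
}

#' Assign three-class labels under a discretization scheme
#'
#' Classes follow the fixed boundary convention `[min, c1)` for class 1,
#' `[c1, c2]` for class 2 and `(c2, max]` for class 3; `NA` stays `NA`.
#'
#' @param values numeric vector (finite or `NA`).
#' @param scheme a \linkS4class{DiscretizationScheme}.
#' @return integer labels in `{1, 2, 3}` (with `NA` preserved).
#' @export
assignClasses <- function(values, scheme) {
  if (any(is.infinite(values) | is.nan(values)))
    stop("non-finite values cannot be classified")
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  out[ok] <- classifyAt(values[ok], scheme@cutpoints)
  out
}

#' @rdname cutpoints
#' @export
setMethod("cutpoints", "DiscretizationScheme", function(x) x@cutpoints)

setMethod("show", "DiscretizationScheme", function(object) {
  cat(sprintf("DiscretizationScheme[%s]: classes [min,%.1f) [%.1f,%.1f] (%.1f,max], method=%s\n",
              object@variable, object@cutpoints[1], object@cutpoints[1],
              object@cutpoints[2], object@cutpoints[2], object@method))
})

#' Class-balance report for discretized labels
#'
#' @param labels integer class labels in `{1, 2, 3}` (`NA` ignored).
#' @return list with `proportions` (summing to 1), `ratio` (max/min, `Inf`
#'   when a class is empty — reported with a warning, as is any ratio above
#'   3).
#' @export
balanceReport <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labels to report on")
  counts <- tabulate(labels, 3)
  prop <- counts / sum(counts)
  ratio <- if (min(counts) == 0) Inf else max(counts) / min(counts)
  if (!is.finite(ratio) || ratio > 3)
    warning(sprintf("classes are unbalanced (max/min ratio %.2f)", ratio))
  list(proportions = prop, ratio = ratio, counts = counts)
}

#' Serialize / restore a discretization scheme as JSON
#'
#' @param scheme a \linkS4class{DiscretizationScheme}.
#' @param file output path.
#' @export
writeScheme <- function(scheme, file) {
  jsonlite::write_json(list(
    variable = scheme@variable, cutpoints = scheme@cutpoints,
    bin_width = scheme@binWidth, range = scheme@histRange,
    class_counts = scheme@classCounts, method = scheme@method),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeScheme
#' @export
readScheme <- function(file) {
  s <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("DiscretizationScheme", variable = s$variable,
      cutpoints = as.numeric(s$cutpoints), binWidth = as.numeric(s$bin_width),
      histRange = as.numeric(s$range), classCounts = as.integer(s$class_counts),
      method = s$method)
}

# discretize every column of a table: peak-based where the distribution shows
# two usable peaks, tercile fallback otherwise; returns integer matrix + schemes
discretizeTable <- function(x, binWidth = NULL) {
  vals <- if (is(x, "LabTable")) labValues(x) else as.matrix(x)
  schemes <- list()
  out <- matrix(NA_integer_, nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  for (v in colnames(vals)) {
    obs <- vals[, v]
    sch <- tryCatch(peakCutpoints(obs[!is.na(obs)], binWidth = binWidth,
                                  variable = v),
                    error = function(e) quantileCutpoints(obs[!is.na(obs)], v))
    schemes[[v]] <- sch
    out[, v] <- assignClasses(obs, sch)
  }
  list(classes = out, schemes = schemes)
}
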