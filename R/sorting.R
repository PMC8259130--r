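## Gating and sort-performance metrics.

#' Otsu's threshold for a 1D feature
#'
#' Convenience helper placing a gate boundary at the valley of a bimodal
#' feature histogram by maximizing the between-class variance.
#'
#' @param x numeric values (NAs dropped)
#' @param nbins histogram resolution
#' @return the threshold value
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least two finite values")
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  bcv <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  ## an empty valley makes the criterion flat over the whole gap; take
  ## the middle of the maximal plateau, not its first bin
  sel <- which(bcv >= max(bcv) * (1 - 1e-9))
  mids[sel[ceiling(length(sel) / 2)]]
}

#' Build a gate from the valley of a feature histogram
#'
#' @param features feature table from \code{extractFeatures()}
#' @param axis feature column to gate on
#' @param target class label the gate selects
#' @param side "above" gates values above the valley, "below" under it
#' @param logScale threshold on the log scale (the default for strictly
#'   positive data; size-like features are multiplicative, and the log
#'   scale keeps the valley out of the tighter mode's tail)
#' @return a \linkS4class{GateSpec}
#' @export
gateFromValley <- function(features, axis, target,
                           side = c("above", "below"), logScale = NULL) {
  side <- match.arg(side)
  x <- features[[axis]][features$flag == "ok"]
  if (is.null(logScale)) logScale <- all(x > 0, na.rm = TRUE)
  th <- if (logScale) exp(otsuThreshold(log(x))) else otsuThreshold(x)
  bounds <- if (side == "above") c(th, Inf) else c(-Inf, th)
  new("GateSpec", axes = setNames(list(bounds), axis), target = target)
}

#' Build a rectangular gate from a class-separated scatter
#'
#' Mirrors the practice of drawing a gate between two labeled
#' populations on a feature scatter: on each axis the boundary sits
#' midway between the target's lower quantile and the background's upper
#' quantile (or mirrored when the target lies below).
#'
#' @param features feature table with a truthLabel column (or labels
#'   supplied separately)
#' @param axes feature columns to gate on (1 or 2)
#' @param target class label the gate selects
#' @param labels class labels per event (defaults to truthLabel)
#' @param q quantile used for the population edges
#' @return a \linkS4class{GateSpec}
#' @export
gateFromScatter <- function(features, axes, target, labels = NULL,
                            q = 0.01) {
  if (is.null(labels)) labels <- features$truthLabel
  ok <- features$flag == "ok" & !is.na(labels)
  bounds <- lapply(axes, function(ax) {
    x <- features[[ax]][ok]
    isT <- labels[ok] == target
    if (!any(isT) || all(isT)) stop("need both target and background events")
    tLo <- quantile(x[isT], q, names = FALSE)
    tHi <- quantile(x[isT], 1 - q, names = FALSE)
    bLo <- quantile(x[!isT], q, names = FALSE)
    bHi <- quantile(x[!isT], 1 - q, names = FALSE)
    if (median(x[isT]) >= median(x[!isT])) {
      c((tLo + bHi) / 2, Inf)
    } else {
      c(-Inf, (tHi + bLo) / 2)
    }
  })
  new("GateSpec", axes = setNames(bounds, axes), target = target)
}

#' Events selected by a gate
#'
#' @param features feature table
#' @param gate a \linkS4class{GateSpec}
#' @return logical vector, TRUE where the event falls inside the gate
#'   (flagged events are never sorted)
#' @export
gateMembership <- function(features, gate) {
  miss <- setdiff(names(gate@axes), names(features))
  if (length(miss)) {
    stop("gate axes not in the feature table: ", paste(miss, collapse = ", "),
         "; available: ", paste(names(features), collapse = ", "))
  }
  inside <- features$flag == "ok"
  for (ax in names(gate@axes)) {
    b <- gate@axes[[ax]]
    v <- features[[ax]]
    inside <- inside & !is.na(v) & v >= b[1] & v <= b[2]
  }
  inside
}

#' Apply a gate and score the emulated sort
#'
#' Events inside the gate are "sorted". Against the ground-truth labels
#' this yields purity = 100 TP / (TP + FP), yield = 100 TP / (total
#' target events), and enrichment = post-sort target:background odds
#' over pre-sort odds (infinite when no background object is sorted).
#'
#' @param features feature table with truth labels
#' @param gate a \linkS4class{GateSpec}
#' @param labels class labels per event (defaults to truthLabel)
#' @return a \linkS4class{SortReport}
#' @export
applyGateAndScore <- function(features, gate, labels = NULL) {
  if (is.null(labels)) labels <- features$truthLabel
  inside <- gateMembership(features, gate)
  isT <- !is.na(labels) & labels == gate@target
  tp <- sum(inside & isT); fp <- sum(inside & !isT)
  fn <- sum(!inside & isT); tn <- sum(!inside & !isT)
  counts <- c(sortedTarget = tp, sortedOther = fp,
              unsortedTarget = fn, unsortedOther = tn)
  purity <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  yield <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  oddsBefore <- (tp + fn) / (fp + tn)
  oddsAfter <- if (fp > 0) tp / fp else Inf
  enrich <- oddsAfter / oddsBefore
  new("SortReport", counts = setNames(as.integer(counts), names(counts)),
      purity = purity, yield = yield, enrichment = enrich,
      target = gate@target)
}

#' Sort purity from printed sorted counts
#'
#' @param nTarget number of sorted objects verified as targets
#' @param nTotal total number of sorted objects verified
#' @return purity in percent
#' @export
purityFromCounts <- function(nTarget, nTotal) {
  stopifnot(nTotal > 0, nTarget >= 0, nTarget <= nTotal)
  100 * nTarget / nTotal
}
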