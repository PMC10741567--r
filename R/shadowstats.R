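# Radial-profile statistics of a cell's shadow pattern. The four classical
# lens-free shadow parameters: CMV (central maxima value), PPD (intensity
# drop from the centre to the first dark concentric ring), MMD (radius of
# that ring) and SMD (angular dispersion of MMD), plus the PPD label gate
# and Tukey boxplot summaries.

#' Radial intensity profile of a cell crop
#'
#' Averages pixel intensities in integer radial bins around the crop centre
#' (position (15, 15) of a 30x30 crop): bin r collects pixels whose
#' Euclidean distance from the centre rounds to r, for r = 0..14.
#'
#' @param crop a square intensity matrix (30x30 in the standard pipeline).
#' @return a data.frame with columns `radius` (0..14) and `intensity`.
#' @examples
#' radialProfile(matrix(100, 30, 30))
#' @export
radialProfile <- function(crop) {
  stopifnot(is.matrix(crop), nrow(crop) == ncol(crop))
  n <- nrow(crop)
  ctr <- n %/% 2            # 15 for n = 30
  rmax <- ctr - 1           # 14
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  r <- round(d)
  intensity <- vapply(0:rmax, function(k) mean(crop[r == k]), numeric(1))
  data.frame(radius = 0:rmax, intensity = intensity)
}

# 3-point moving average with shrinking windows at the ends
smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - 1):min(n, i + 1)]), numeric(1))
}

# first strict local minimum of the smoothed profile, searched over radii
# search[1]..search[2]; returns NA when none exists
firstMinimumRadius <- function(intensity, search = c(2, 14)) {
  s <- smooth3(intensity)
  n <- length(intensity)
  for (r in search[1]:min(search[2], n - 2)) {
    i <- r + 1  # 1-based index of radius r
    if (s[i] < s[i - 1] && s[i] < s[i + 1]) return(r)
  }
  NA_integer_
}

#' Shadow-pattern parameters of a crop or profile
#'
#' Computes CMV (intensity at radius 0), MMD (radius of the first dark
#' concentric ring: the first strict local minimum of the 3-point-smoothed
#' radial profile, refined to the raw-profile minimum within one bin), PPD
#' (CMV minus the raw intensity at MMD), and — when a full crop is supplied —
#' SMD (population standard deviation of per-sector MMD over 8 equal angular
#' sectors; sectors without a minimum are excluded). When the profile has no
#' interior minimum the result is flagged invalid with PPD 0 and MMD/SMD NA.
#'
#' @param x a crop matrix or a radial profile data.frame from
#'   [radialProfile()].
#' @return a one-row data.frame: `cmv`, `ppd`, `mmd`, `smd`, `valid`.
#' @examples
#' prof <- data.frame(radius = 0:14,
#'                    intensity = c(156.8, 150, 140, 128, 118, 112.5,
#'                                  116, 122, 128, 132, 134, 135, 135,
#'                                  135, 135))
#' computeShadowParams(prof)$ppd   # 44.3
#' @export
computeShadowParams <- function(x) {
  if (is.matrix(x)) {
    prof <- radialProfile(x)
    smd <- sectorMMDSD(x)
  } else {
    prof <- x
    smd <- NA_real_
  }
  stopifnot(all(c("radius", "intensity") %in% names(prof)))
  if (is.unsorted(prof$radius, strictly = TRUE) || prof$radius[1] != 0)
    stop("profile radii must increase strictly from 0")
  int <- prof$intensity
  cmv <- int[1]
  mmd <- firstMinimumRadius(int)
  if (is.na(mmd)) {
    return(data.frame(cmv = cmv, ppd = 0, mmd = NA_real_, smd = NA_real_,
                      valid = FALSE))
  }
  cand <- intersect((mmd - 1):(mmd + 1), seq_along(int) - 1)
  cand <- cand[cand >= 1]
  mmd <- cand[which.min(int[cand + 1])]
  data.frame(cmv = cmv, ppd = cmv - int[mmd + 1], mmd = as.numeric(mmd),
             smd = smd, valid = TRUE)
}

# SMD: population SD of the per-sector first-minimum radius over 8 equal
# angular sectors (the centre pixel joins every sector at radius 0)
sectorMMDSD <- function(crop) {
  n <- nrow(crop)
  ctr <- n %/% 2
  rmax <- ctr - 1
  dr <- outer(seq_len(n) - ctr, rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - ctr)
  r <- round(sqrt(dr^2 + dc^2))
  ang <- atan2(dr, dc)
  sector <- pmin(8, floor((ang + pi) / (2 * pi / 8)) + 1)
  mmds <- numeric(0)
  for (s in seq_len(8)) {
    int <- vapply(0:rmax, function(k) {
      sel <- r == k & (sector == s | k == 0)
      if (any(sel)) mean(crop[sel]) else NA_real_
    }, numeric(1))
    # carry the last observed value across empty bins near the centre
    for (i in seq_along(int))
      if (is.na(int[i])) int[i] <- int[max(1, i - 1)]
    m <- firstMinimumRadius(int)
    if (!is.na(m)) mmds <- c(mmds, m)
  }
  if (length(mmds) < 2) return(NA_real_)
  sqrt(mean((mmds - mean(mmds))^2))
}

#' Gate shadow parameters on the PPD statistic
#'
#' Keeps rows whose PPD lies in the closed interval [lo, hi] (default 40 to
#' 60 counts, the gate that selects CD34+-like patterns) and are flagged
#' valid.
#'
#' @param params data.frame with at least `ppd` and `valid` columns (as from
#'   [computeShadowParams()] row-bound over crops).
#' @param lo,hi gate bounds, counts.
#' @return the filtered data.frame.
#' @export
ppdGate <- function(params, lo = 40, hi = 60) {
  stopifnot(all(c("ppd", "valid") %in% names(params)))
  params[params$valid & params$ppd >= lo & params$ppd <= hi, , drop = FALSE]
}

#' PPD-gate baseline classifier
#'
#' Labels a crop CD34_POS when its PPD falls inside the gate and RESIDUAL
#' otherwise — the single-statistic decision rule that the convolutional
#' classifier generalises. Used as a floor in evaluation studies.
#'
#' @param crops list of 30x30 crop matrices.
#' @param lo,hi PPD gate bounds, counts.
#' @return character vector of labels.
#' @export
ppdBaseline <- function(crops, lo = 40, hi = 60) {
  vapply(crops, function(cr) {
    p <- computeShadowParams(cr)
    if (p$valid && p$ppd >= lo && p$ppd <= hi) "CD34_POS" else "RESIDUAL"
  }, character(1))
}

#' Tukey boxplot summary of a set of values
#'
#' Quartiles by linear interpolation of order statistics (quantile type 7),
#' IQR, Tukey fences at 1.5 IQR, and the values flagged as outliers.
#'
#' @param values numeric vector, length >= 1.
#' @return a list: `q1`, `median`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `outliers`, `kept`.
#' @examples
#' boxplotSummary(1:8)$iqr   # 3.5
#' @export
boxplotSummary <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  out <- values[values < lf | values > uf]
  list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       lower_fence = lf, upper_fence = uf,
       outliers = out, kept = values[values >= lf & values <= uf])
}
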