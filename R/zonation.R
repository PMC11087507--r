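#' Convert line-profile positions to percent of the CV-PP axis
#'
#' Affine rescaling of positions so 0 is the central-vein edge and 100 the
#' portal-vein edge: \eqn{p \to 100 (p - p_{min}) / (p_{max} - p_{min})}.
#' Idempotent on already-percentized profiles. Profiles drawn portal-first
#' can be flagged with \code{reverse = TRUE} and are flipped before
#' rescaling.
#'
#' @param profile data.frame with columns \code{position_um} (strictly
#'   increasing, >= 2 samples) and \code{intensity}; extra columns
#'   (\code{profile_id}, \code{channel}) are preserved. Multi-profile
#'   frames are percentized per \code{profile_id}.
#' @param reverse logical: profile was drawn portal-to-central.
#' @return The profile with an added/updated \code{position_pct} column.
#' @export
percentize <- function(profile, reverse = FALSE) {
  stopifnot(is.data.frame(profile))
  one <- function(p) {
    pos <- p$position_um
    if (length(pos) < 2L) stop("a profile needs at least 2 samples")
    if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
    span <- max(pos) - min(pos)
    if (span <= 0) stop("zero-length line")
    pct <- 100 * (pos - min(pos)) / span
    if (reverse) pct <- 100 - pct
    p$position_pct <- pct
    p
  }
  if ("profile_id" %in% names(profile) &&
      length(unique(profile$profile_id)) > 1L) {
    parts <- split(profile, profile$profile_id)
    out <- do.call(rbind, lapply(parts, one))
    rownames(out) <- NULL
    out
  } else one(profile)
}

#' Bin a percentized profile
#'
#' Bins \code{[k w, (k+1) w)} with the last bin closed at 100; bin labels
#' are lower edges (0, 5, ..., 95 for the default width 5). Per-bin mean
#' intensity and sample counts are returned; empty bins carry NA means and
#' are flagged. Counts always sum to the sample count.
#'
#' @param profile a percentized profile (has \code{position_pct} in
#'   [0, 100]) for a single profile id.
#' @param binWidth bin width in percent (default 5).
#' @return data.frame: \code{bin} (lower edge), \code{mean_intensity},
#'   \code{n}, \code{empty}.
#' @export
binProfile <- function(profile, binWidth = 5) {
  stopifnot("position_pct" %in% names(profile))
  p <- profile$position_pct
  if (any(p < 0 | p > 100)) stop("positions outside [0, 100]")
  edges <- seq(0, 100, by = binWidth)
  k <- findInterval(p, edges, rightmost.closed = TRUE)
  lev <- seq_len(length(edges) - 1L)
  n <- as.integer(table(factor(k, levels = lev)))
  sums <- tapply(profile$intensity, factor(k, levels = lev), sum)
  data.frame(bin = edges[-length(edges)],
             mean_intensity = as.numeric(sums) / ifelse(n > 0, n, NA),
             n = n, empty = n == 0L)
}

#' Zone summary across profiles
#'
#' Summarizes the pericentral and periportal signal as the across-profile
#' mean (± sd / sem) of the binned intensity at two named bins — by
#' default bins 10 and 90 (lower-edge labels, i.e. [10, 15) and [90, 95)),
#' representing the central- and portal-vein ends.
#'
#' @param binnedProfiles list of [binProfile()] outputs (optionally named
#'   by profile), or a single binned profile.
#' @param cvBin,ppBin bin labels for the central and portal zones.
#' @return data.frame with one row per zone: \code{zone, bin, mean, sd,
#'   sem, n_profiles}.
#' @export
zoneSummary <- function(binnedProfiles, cvBin = 10, ppBin = 90) {
  if (is.data.frame(binnedProfiles)) binnedProfiles <- list(binnedProfiles)
  pull <- function(bin) {
    v <- vapply(binnedProfiles, function(b) {
      row <- b[b$bin == bin, ]
      if (!nrow(row)) stop("bin ", bin, " not present")
      row$mean_intensity
    }, numeric(1))
    v[!is.na(v)]
  }
  cv <- pull(cvBin); pp <- pull(ppBin)
  if (!length(cv)) stop("bin ", cvBin, " empty in all profiles")
  if (!length(pp)) stop("bin ", ppBin, " empty in all profiles")
  mk <- function(zone, bin, v)
    data.frame(zone = zone, bin = bin, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n_profiles = length(v))
  rbind(mk("central", cvBin, cv), mk("portal", ppBin, pp))
}
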