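#' Permutation test on pooled per-object metrics
#'
#' Compares two condition groups by the two-sided difference of means
#' (default) under label permutation. Values are pooled within each group
#' (cells within a condition are pooled, matching how grouped FIB-SEM
#' metrics are tested); permutation can shuffle at the object level
#' (default) or at the cell level to respect within-cell correlation.
#'
#' Monte-Carlo sampling reports the +1-corrected empirical p-value
#' \deqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (n_{perm} + 1),} which
#' can never be 0. When the total number of units is small (or
#' \code{exact = TRUE}) all label assignments are enumerated instead and
#' the uncorrected proportion over the complete enumeration (which
#' includes the observed assignment) is returned.
#'
#' @param a,b numeric vectors of per-object values, or (for
#'   \code{unit = "cell"}) lists of per-cell numeric vectors.
#' @param statistic only \code{"diff_of_means"} (two-sided absolute
#'   difference of group means) is built in; a function
#'   \code{f(valuesA, valuesB)} may be supplied (its absolute value is
#'   compared two-sidedly).
#' @param nPerm Monte-Carlo permutations (default 1e5).
#' @param unit "object" or "cell".
#' @param seed RNG seed; every call is deterministic given it.
#' @param exact force (TRUE) or forbid (FALSE) exhaustive enumeration;
#'   default NULL enumerates when there are at most 12 units.
#' @return list with class \code{"PermutationResult"}: \code{observed},
#'   \code{p}, \code{n_perm} (permutations drawn or splits enumerated),
#'   \code{method}, \code{unit}, \code{seed}.
#' @export
permutationTest <- function(a, b, statistic = "diff_of_means",
                            nPerm = 1e5, unit = c("object", "cell"),
                            seed = 1L, exact = NULL) {
  unit <- match.arg(unit)
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (unit == "cell") {
    if (!is.list(a) || !is.list(b)) stop("cell-level test needs lists of per-cell values")
    unitsA <- a; unitsB <- b
  } else {
    unitsA <- as.list(unlist(a)); unitsB <- as.list(unlist(b))
  }
  if (!length(unitsA) || !length(unitsB)) stop("both groups must be non-empty")
  vals <- c(unitsA, unitsB)
  na <- length(unitsA); n <- length(vals)
  statFun <- if (is.function(statistic)) {
    function(ia) abs(statistic(unlist(vals[ia]), unlist(vals[-ia])))
  } else {
    match.arg(statistic, "diff_of_means")
    function(ia) abs(mean(unlist(vals[ia])) - mean(unlist(vals[-ia])))
  }
  obs <- statFun(seq_len(na))
  eps <- 1e-12 * (obs + 1)
  if (is.null(exact)) exact <- n <= 12
  if (exact) {
    splits <- utils::combn(n, na)
    stats <- apply(splits, 2, statFun)
    p <- mean(stats >= obs - eps)
    return(structure(list(observed = obs, p = p, n_perm = ncol(splits),
                          method = "exhaustive", unit = unit, seed = seed),
                     class = "PermutationResult"))
  }
  count <- withr::with_seed(seed, {
    if (!is.function(statistic) && unit == "object") {
      .perm_count_cpp(unlist(vals), na, as.integer(nPerm))
    } else {
      sum(vapply(seq_len(nPerm), function(i)
        statFun(sample.int(n, na)) >= obs - eps, logical(1)))
    }
  })
  structure(list(observed = obs, p = (1 + count) / (nPerm + 1),
                 n_perm = nPerm, method = "monte_carlo", unit = unit,
                 seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("Permutation test (", x$method, ", unit = ", x$unit, ")\n",
      "  |T| observed = ", signif(x$observed, 5),
      ",  p = ", signif(x$p, 5), "  (", x$n_perm,
      if (x$method == "exhaustive") " splits)" else " permutations)",
      "\n", sep = "")
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples with replacement \code{nBoot} times and reports the
#' percentile interval with linearly interpolated quantiles across the
#' ordered replicate statistics. The field-default \code{nBoot = 20} is
#' honored (it is how effect-size CIs accompany the permutation tests)
#' but is coarse for percentile intervals; raise it for calibrated
#' coverage.
#'
#' @param values numeric vector, length >= 2.
#' @param statistic function of a numeric vector (default mean).
#' @param nBoot bootstrap replicates (default 20).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with class \code{"BootstrapCI"}: \code{estimate},
#'   \code{lower}, \code{upper}, \code{level}, \code{n_boot}, \code{seed}.
#' @export
bootstrapCI <- function(values, statistic = mean, nBoot = 20,
                        level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values")
  reps <- withr::with_seed(seed, {
    n <- length(values)
    vapply(seq_len(nBoot), function(i)
      statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(estimate = statistic(values), lower = qs[1], upper = qs[2],
                 level = level, n_boot = nBoot, seed = seed),
            class = "BootstrapCI")
}

#' @export
print.BootstrapCI <- function(x, ...) {
  cat("Bootstrap ", x$level * 100, "% CI (n_boot = ", x$n_boot, "): ",
      signif(x$estimate, 5), " [", signif(x$lower, 5), ", ",
      signif(x$upper, 5), "]\n", sep = "")
  invisible(x)
}

#' Frequency distribution over fixed bin edges
#'
#' Half-open bins \code{[e_i, e_{i+1})} with the last bin closed; values
#' outside the edges are not counted. Relative frequencies divide by the
#' total number of values, so they sum to 1 exactly when all values fall
#' in range.
#'
#' @param values numeric vector.
#' @param binEdges strictly increasing edge vector.
#' @return data.frame: \code{lo, hi, count, frequency}.
#' @export
freqDistribution <- function(values, binEdges) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  k <- findInterval(values, binEdges, rightmost.closed = TRUE)
  k[k == length(binEdges)] <- 0L  # above top edge (rightmost.closed handled)
  lev <- seq_len(length(binEdges) - 1L)
  counts <- as.integer(table(factor(k[k > 0L], levels = lev)))
  data.frame(lo = binEdges[-length(binEdges)], hi = binEdges[-1],
             count = counts,
             frequency = if (length(values)) counts / length(values) else
               rep(0, length(lev)))
}
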