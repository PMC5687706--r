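# Threshold-based connectivity and tail-distribution characterization of
# domain interaction networks: power-law (cis) versus exponential (trans).

#' Interaction threshold from the trans distribution
#'
#' Returns the requested percentile of a pooled interaction distribution
#' (linear-interpolation convention). Interactions below the lowest
#' quartile of the genome-wide trans pool are treated as noise when
#' defining network edges.
#'
#' @param pool Numeric vector of interaction intensities.
#' @param percentile Percentile in [0, 100].
#' @return The threshold intensity.
#' @export
interaction_threshold <- function(pool, percentile = 25) {
  if (length(pool) == 0L) stop("empty interaction pool")
  if (percentile < 0 || percentile > 100) {
    stop("percentile must be in [0, 100]")
  }
  unname(stats::quantile(pool, percentile / 100, type = 7))
}

#' Normalized degree of connectivity
#'
#' An edge links two domains when I(a, b) strictly exceeds the threshold.
#' Each node's degree is normalized by its number of possible partners:
#' N - 1 within a chromosome (self excluded), or the size of the partner
#' chromosome's domain set for trans networks. A complete network has
#' n = 1.
#'
#' @param net A \code{\link{domain_interaction_matrix}}.
#' @param threshold Intensity threshold (>= 0).
#' @param denominator \code{"partners"} (N - 1 for cis; default) or
#'   \code{"total"} (N, the raw domain count).
#' @return A list with \code{threshold}, \code{degree} (named per-node
#'   normalized degrees, rows then columns for trans) and \code{n_mean}.
#' @export
normalized_degree <- function(net, threshold,
                              denominator = c("partners", "total")) {
  denominator <- match.arg(denominator)
  v <- net$values
  if (length(v) == 0L) stop("empty network")
  edge <- !is.na(v) & v > threshold
  if (net$kind == "cis") {
    n <- nrow(v)
    denom <- if (denominator == "partners") n - 1L else n
    deg <- rowSums(edge) / denom
  } else {
    deg_row <- rowSums(edge) / ncol(v)
    deg_col <- colSums(edge) / nrow(v)
    deg <- c(deg_row, deg_col)
  }
  list(threshold = threshold, degree = deg, n_mean = mean(deg))
}

#' Average connectivity over a set of networks
#'
#' Applies \code{\link{normalized_degree}} to each network and averages
#' the per-network mean normalized degrees.
#'
#' @inheritParams normalized_degree
#' @param nets List of \code{domain_interaction_matrix} objects.
#' @return A list with \code{threshold}, per-network means and the grand
#'   mean \code{n_mean}.
#' @export
connectivity <- function(nets, threshold,
                         denominator = c("partners", "total")) {
  denominator <- match.arg(denominator)
  per <- vapply(nets, function(net) {
    normalized_degree(net, threshold, denominator)$n_mean
  }, numeric(1))
  list(threshold = threshold, per_network = per, n_mean = mean(per))
}

tail_fit_result <- function(family, converged, gamma = NA_real_,
                            I0 = NA_real_, xmin = NA_real_,
                            r_squared = NA_real_, ks_distance = NA_real_,
                            n_tail = NA_integer_, extra = list()) {
  structure(c(list(family = family, converged = converged, gamma = gamma,
                   I0 = I0, xmin = xmin, r_squared = r_squared,
                   ks_distance = ks_distance, n_tail = n_tail), extra),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("tail_fit (%s): not converged\n", x$family))
    return(invisible(x))
  }
  par <- if (x$family == "power_law") sprintf("gamma = %.4f", x$gamma)
         else sprintf("I0 = %.4g", x$I0)
  cat(sprintf("tail_fit (%s): %s, xmin = %.4g, n_tail = %d, R2 = %.4f, KS = %.4f\n",
              x$family, par, x$xmin, x$n_tail, x$r_squared, x$ks_distance))
  invisible(x)
}

# Continuous power-law MLE at fixed xmin: gamma = 1 + n / sum(log(x/xmin)).
powerlaw_mle <- function(tail, xmin) {
  1 + length(tail) / sum(log(tail / xmin))
}

powerlaw_ks <- function(tail, xmin, gamma) {
  x <- sort(tail)
  n <- length(x)
  theor <- 1 - (x / xmin)^(1 - gamma)
  max(pmax(abs(seq_len(n) / n - theor), abs((seq_len(n) - 1) / n - theor)))
}

# Least-squares R^2 of log10 density against a predictor over binned tail
# data; bins with no observations are dropped.
binned_log_density <- function(tail, breaks) {
  cnt <- graphics::hist(tail, breaks = breaks, plot = FALSE)$counts
  width <- diff(breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- cnt > 0
  data.frame(mid = mids[keep],
             dens = cnt[keep] / (length(tail) * width[keep]))
}

log_bins <- function(tail, n_bins) {
  exp(seq(log(min(tail)), log(max(tail)), length.out = n_bins + 1))
}

r2_of_fit <- function(obs, pred) {
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / tss
}

#' Fit a power-law tail
#'
#' Continuous maximum-likelihood fit of P(I) ~ I^-gamma to the tail of an
#' interaction-intensity sample. Unless \code{xmin} is supplied, the tail
#' start is chosen to minimize the Kolmogorov-Smirnov distance between
#' the data and the fitted model (Clauset-style scan over candidate
#' values). The reported R^2 is that of the straight-line fit of log10
#' density against log10 I on logarithmic bins of the tail — the metric
#' used to compare distribution families.
#'
#' @param values Positive interaction intensities (>= \code{n_min} of
#'   them required).
#' @param xmin Optional fixed tail start; default: KS-optimal scan.
#' @param n_min Minimum sample size.
#' @param n_candidates Number of candidate xmin values scanned.
#' @param n_bins Logarithmic bins used for the R^2 diagnostic.
#' @return A \code{tail_fit} with \code{family = "power_law"}.
#' @export
fit_power_law <- function(values, xmin = NULL, n_min = 50L,
                          n_candidates = 100L, n_bins = 25L) {
  x <- sort(values[is.finite(values) & values > 0])
  if (length(x) < n_min || max(x) == min(x)) {
    return(tail_fit_result("power_law", converged = FALSE))
  }
  if (is.null(xmin)) {
    # candidates: subsample of order statistics, keeping >= 10% in the tail
    hi <- max(1L, floor(0.9 * length(x)))
    cand <- unique(x[unique(round(seq(1L, hi, length.out = n_candidates)))])
  } else {
    cand <- xmin
  }
  best <- NULL
  for (xm in cand) {
    tail <- x[x >= xm]
    if (length(tail) < max(10L, n_min / 5) || max(tail) == xm) next
    g <- powerlaw_mle(tail, xm)
    ks <- powerlaw_ks(tail, xm, g)
    if (is.null(best) || ks < best$ks) {
      best <- list(xm = xm, g = g, ks = ks, n = length(tail))
    }
  }
  if (is.null(best) || best$g <= 1) {
    return(tail_fit_result("power_law", converged = FALSE))
  }
  tail <- x[x >= best$xm]
  bl <- binned_log_density(tail, log_bins(tail, n_bins))
  r2 <- NA_real_
  if (nrow(bl) >= 3L) {
    fit <- stats::lm(log10(dens) ~ log10(mid), data = bl)
    r2 <- r2_of_fit(log10(bl$dens), stats::fitted(fit))
  }
  tail_fit_result("power_law", converged = TRUE, gamma = best$g,
                  xmin = best$xm, r_squared = r2, ks_distance = best$ks,
                  n_tail = best$n,
                  extra = list(se_gamma = (best$g - 1) / sqrt(best$n)))
}

#' Fit an exponential tail
#'
#' Fits P(I) ~ exp(-I / I0) to the tail of an interaction-intensity
#' sample. The reported I0 is the maximum-likelihood estimate (mean
#' excess over the tail start). A nonlinear least-squares fit of
#' A exp(-I/I0) to the binned tail density provides a cross-check
#' estimate \code{I0_lsq}; the R^2 diagnostic is that of the
#' straight-line fit of log10 density against I on logarithmic bins of
#' the tail (the lin-log representation in which an exponential is a
#' straight line), directly comparable with the power-law R^2 computed
#' on the same binning. The tail start defaults to the sample median.
#'
#' @param values Positive interaction intensities.
#' @param xmin Optional tail start; default: sample median.
#' @param n_min Minimum sample size.
#' @param n_bins Logarithmic bins used for the binned fits.
#' @return A \code{tail_fit} with \code{family = "exponential"}.
#' @export
fit_exponential <- function(values, xmin = NULL, n_min = 50L, n_bins = 25L) {
  x <- values[is.finite(values) & values > 0]
  if (length(x) < n_min || max(x) == min(x)) {
    return(tail_fit_result("exponential", converged = FALSE))
  }
  if (is.null(xmin)) xmin <- stats::median(x)
  tail <- x[x >= xmin]
  if (length(tail) < max(10L, n_min / 5) || max(tail) == min(tail)) {
    return(tail_fit_result("exponential", converged = FALSE))
  }
  i0_mle <- mean(tail - xmin)
  if (i0_mle <= 0) return(tail_fit_result("exponential", converged = FALSE))
  bl <- binned_log_density(tail, log_bins(tail, n_bins))
  i0_lsq <- NA_real_; r2 <- NA_real_; lsq_ok <- FALSE
  if (nrow(bl) >= 3L) {
    lin <- stats::lm(log10(dens) ~ mid, data = bl)
    slope <- stats::coef(lin)[2L]
    r2 <- r2_of_fit(log10(bl$dens), stats::fitted(lin))
    fit <- try(minpack.lm::nlsLM(
      dens ~ A * exp(-mid / I0), data = bl,
      start = list(A = exp(xmin / i0_mle) / i0_mle, I0 = i0_mle),
      lower = c(A = 1e-300, I0 = i0_mle * 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      i0_lsq <- unname(stats::coef(fit)["I0"])
      lsq_ok <- TRUE
    } else if (is.finite(slope) && slope < 0) {
      i0_lsq <- unname(-1 / (slope * log(10)))
    }
  }
  tail_fit_result("exponential", converged = TRUE, I0 = i0_mle,
                  xmin = xmin, r_squared = r2, n_tail = length(tail),
                  extra = list(I0_lsq = i0_lsq, lsq_converged = lsq_ok,
                               se_I0 = i0_mle / sqrt(length(tail))))
}

#' Compare power-law and exponential tail models
#'
#' Fits both families to the same sample and classifies by the higher
#' binned-fit R^2; a non-convergent fit loses automatically.
#'
#' @param values Positive interaction intensities.
#' @param ... Passed to the two fitting routines.
#' @return A list with \code{classification} ("power_law",
#'   "exponential" or "undetermined") and both \code{tail_fit}s.
#' @export
compare_tail_models <- function(values, ...) {
  pl <- fit_power_law(values, ...)
  ex <- fit_exponential(values, ...)
  r2p <- if (pl$converged && is.finite(pl$r_squared)) pl$r_squared else -Inf
  r2e <- if (ex$converged && is.finite(ex$r_squared)) ex$r_squared else -Inf
  cls <- if (r2p == -Inf && r2e == -Inf) "undetermined"
         else if (r2p >= r2e) "power_law" else "exponential"
  list(classification = cls, power_law = pl, exponential = ex)
}

#' Rescale per-chromosome intensity distributions for overlay
#'
#' Log-bins each chromosome's intensity distribution, then scales I by
#' the chromosome median (I0) and the density by its value at that
#' median (P0). Chromosomes sharing the same distribution shape collapse
#' onto a single curve regardless of overall intensity scale.
#'
#' @param pools Named list of per-chromosome intensity vectors.
#' @param n_bins Number of logarithmic bins.
#' @return A data.frame with columns \code{chrom}, \code{I_scaled},
#'   \code{P_scaled}.
#' @export
rescale_collapse <- function(pools, n_bins = 25L) {
  if (length(pools) < 2L) stop("need at least two distributions")
  out <- lapply(names(pools), function(nm) {
    x <- pools[[nm]]
    x <- x[is.finite(x) & x > 0]
    bl <- binned_log_density(x, log_bins(x, n_bins))
    I0 <- stats::median(x)
    # density at the median, interpolated on the log-log curve
    P0 <- exp(stats::approx(log(bl$mid), log(bl$dens), xout = log(I0),
                            rule = 2)$y)
    data.frame(chrom = nm, I_scaled = bl$mid / I0, P_scaled = bl$dens / P0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
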