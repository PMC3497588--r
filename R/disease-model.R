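# Disease model: tri-modal Gaussian curve over the factor-score
# distribution, data-driven thresholds from component intersections, and
# the partition of factors into association bands.

#' Tri-modal curve parameters
#'
#' Parameters of the three-component Gaussian-shaped curve
#' `f(x) = sum_i alpha_i * exp(-((x - mu_i)/sigma_i)^2)`.
#' Note the exponent carries no 1/2 factor and the amplitudes are not
#' normalized: each component is a curve of height `alpha_i` and
#' half-width `sigma_i` (a Gaussian with standard deviation
#' `sigma_i/sqrt(2)`), not a probability density.  Components are
#' relabeled on construction so that `mu` is ascending.
#'
#' @param alpha Three non-negative scaling factors (peak heights).
#' @param mu Three peak centers in `[-1, 1]`.
#' @param sigma Three positive width parameters.
#' @return An object of class `hgf_trimodal_params`.
#' @export
trimodal_params <- function(alpha, mu, sigma) {
  if (length(alpha) != 3L || length(mu) != 3L || length(sigma) != 3L) {
    hgf_stop("alpha, mu, sigma must each have length 3", "hgf_invalid_input")
  }
  if (any(!is.finite(c(alpha, mu, sigma)))) {
    hgf_stop("parameters must be finite", "hgf_invalid_input")
  }
  if (any(alpha < 0)) hgf_stop("all alpha must be >= 0", "hgf_invalid_input")
  if (any(sigma <= 0)) hgf_stop("all sigma must be > 0", "hgf_invalid_input")
  ord <- order(mu)
  structure(
    list(alpha = as.numeric(alpha[ord]), mu = as.numeric(mu[ord]), sigma = as.numeric(sigma[ord])),
    class = "hgf_trimodal_params"
  )
}

#' @export
print.hgf_trimodal_params <- function(x, ...) {
  cat("<tri-modal parameters>\n")
  for (i in 1:3) {
    cat(sprintf(
      "  component %d: alpha = %.4g, mu = %.4g, sigma = %.4g\n",
      i, x$alpha[[i]], x$mu[[i]], x$sigma[[i]]
    ))
  }
  invisible(x)
}

#' Evaluate the tri-modal curve
#'
#' @param x Numeric vector of scores.
#' @param params An [trimodal_params()] object.
#' @return Non-negative numeric vector, `f(x)`.
#' @export
trimodal_density <- function(x, params) {
  stopifnot(inherits(params, "hgf_trimodal_params"))
  out <- numeric(length(x))
  for (i in 1:3) {
    out <- out + params$alpha[[i]] * exp(-((x - params$mu[[i]]) / params$sigma[[i]])^2)
  }
  out
}

#' Histogram of association scores
#'
#' Equal-width bins spanning the full cosine range `[-1, 1]`.
#'
#' @param scores Numeric vector of cosine scores within `[-1, 1]`.
#' @param n_bins Number of bins (>= 2; default 20).
#' @return An object of class `hgf_histogram`: list with `edges`
#'   (length `n_bins + 1`), `centers`, `heights` (counts).
#' @export
score_histogram <- function(scores, n_bins = 20L) {
  scores <- scores[!is.na(scores)]
  if (any(scores < -1 | scores > 1)) {
    hgf_stop("scores must lie within [-1, 1]", "hgf_invalid_input")
  }
  if (!is.numeric(n_bins) || n_bins < 2L) {
    hgf_stop("n_bins must be >= 2", "hgf_invalid_input")
  }
  n_bins <- as.integer(n_bins)
  width <- 2 / n_bins
  idx <- pmin(floor((scores + 1) / width) + 1L, n_bins)
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  structure(
    list(
      edges = edges,
      centers = (edges[-1L] + edges[-length(edges)]) / 2,
      heights = tabulate(idx, nbins = n_bins)
    ),
    class = "hgf_histogram"
  )
}

histogram_xy <- function(histogram) {
  if (inherits(histogram, "hgf_histogram") ||
    (is.list(histogram) && !is.null(histogram$heights))) {
    x <- histogram$centers
    if (is.null(x) && !is.null(histogram$edges)) {
      e <- histogram$edges
      x <- (e[-1L] + e[-length(e)]) / 2
    }
    return(list(x = as.numeric(x), y = as.numeric(histogram$heights)))
  }
  hgf_stop("histogram must provide centers/edges and heights", "hgf_invalid_input")
}

# Weighted quantiles of bin centers, used for auto-initialization.
hist_quantile <- function(x, w, probs) {
  if (sum(w) == 0) {
    return(rep(mean(x), length(probs)))
  }
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[[1L]]], numeric(1))
}

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total`, with the total sum of squares taken
#' around the observed mean.  Always `<= 1`; undefined (error) when the
#' observed values have zero variance.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Numeric scalar `<= 1`.
#' @export
r_square <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    hgf_stop("observed and predicted must have equal length >= 2", "hgf_invalid_input")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    hgf_stop("R-square undefined: observed values have zero variance", "hgf_undefined")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit the tri-modal curve to a score histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of
#' the tri-modal curve against (bin center, height) pairs, under
#' `alpha >= 0`, `sigma > 0`, `mu` in `[-1, 1]`.  Initialization places
#' the peak centers at the 10th/50th/90th weighted percentiles of the
#' histogram, with widths from the inter-percentile gaps and amplitudes
#' from the corresponding bin heights; `restarts` seeded random
#' perturbations of that start are tried and the best fit by R-square is
#' kept.  Components are relabeled so `mu` is ascending.
#'
#' @param histogram An [score_histogram()] result, or any list with
#'   `centers` (or `edges`) and `heights`.
#' @param init `"auto"` (default) or an [trimodal_params()] start.
#' @param restarts Number of randomized restarts (default 20).
#' @param seed Optional integer seed making the restarts reproducible.
#' @return An object of class `hgf_trimodal_fit`: list with `params`,
#'   `r_square`, `bins` (edges, when known), `heights`, `predicted`.
#' @export
fit_trimodal <- function(histogram, init = "auto", restarts = 20L, seed = NULL) {
  xy <- histogram_xy(histogram)
  x <- xy$x
  y <- xy$y
  if (length(x) < 9L) {
    hgf_stop("need at least 9 bins (9 free parameters)", "hgf_invalid_input")
  }
  if (all(y == 0)) {
    hgf_stop("degenerate histogram: all heights are zero", "hgf_degenerate")
  }
  if (identical(init, "auto")) {
    q <- hist_quantile(x, y, c(0.1, 0.5, 0.9))
    mu0 <- q
    sig0 <- pmax(c((q[2] - q[1]) / 2, (q[3] - q[1]) / 4, (q[3] - q[2]) / 2), 0.02)
    a0 <- pmax(vapply(mu0, function(m) y[which.min(abs(x - m))], numeric(1)), max(y) / 20)
    start <- c(a0, mu0, sig0)
  } else {
    stopifnot(inherits(init, "hgf_trimodal_params"))
    start <- c(init$alpha, init$mu, init$sigma)
  }
  lower <- c(0, 0, 0, -1, -1, -1, 1e-3, 1e-3, 1e-3)
  upper <- c(rep(max(y) * 10 + 1, 3), 1, 1, 1, 2, 2, 2)
  start <- pmin(pmax(start, lower), upper)
  resid_fn <- function(p) {
    y - (p[1] * exp(-((x - p[4]) / p[7])^2) +
      p[2] * exp(-((x - p[5]) / p[8])^2) +
      p[3] * exp(-((x - p[6]) / p[9])^2))
  }
  one_fit <- function(p0) {
    tryCatch(
      {
        f <- minpack.lm::nls.lm(
          par = p0, fn = resid_fn, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 500)
        )
        pred <- y - resid_fn(f$par)
        r2 <- tryCatch(r_square(y, pred), hgf_error = function(e) -Inf)
        list(par = f$par, r2 = r2, deviance = f$deviance)
      },
      error = function(e) NULL
    )
  }
  run_restarts <- function() {
    best <- NULL
    attempts <- list(start)
    for (i in seq_len(max(0L, restarts - 1L))) {
      jitter <- start
      jitter[1:3] <- jitter[1:3] * exp(runif(3, -0.7, 0.7))
      jitter[4:6] <- pmin(pmax(jitter[4:6] + runif(3, -0.15, 0.15), -1), 1)
      jitter[7:9] <- pmin(pmax(jitter[7:9] * exp(runif(3, -0.7, 0.7)), 1e-3), 2)
      attempts[[length(attempts) + 1L]] <- jitter
    }
    for (p0 in attempts) {
      res <- one_fit(p0)
      if (!is.null(res) && (is.null(best) || res$r2 > best$r2)) best <- res
    }
    best
  }
  best <- if (is.null(seed)) run_restarts() else withr::with_seed(seed, run_restarts())
  if (is.null(best) || !is.finite(best$r2)) {
    hgf_stop(
      "tri-modal fit did not converge",
      "hgf_fit_failure",
      best_par = if (!is.null(best)) best$par else NULL,
      residual = if (!is.null(best)) best$deviance else NULL
    )
  }
  p <- best$par
  params <- trimodal_params(p[1:3], p[4:6], p[7:9])
  pred <- trimodal_density(x, params)
  structure(
    list(
      params = params,
      r_square = best$r2,
      bins = if (!is.null(histogram$edges)) histogram$edges else NULL,
      centers = x,
      heights = y,
      predicted = pred
    ),
    class = "hgf_trimodal_fit"
  )
}

#' @export
print.hgf_trimodal_fit <- function(x, ...) {
  cat(sprintf("<tri-modal fit> R-square = %.4f\n", x$r_square))
  print(x$params)
  invisible(x)
}

# Intersection of two weighted Gaussian-shaped components inside the open
# interval (mu_i, mu_j): solve
#   log a_i - ((x-mu_i)/s_i)^2 = log a_j - ((x-mu_j)/s_j)^2
# which is quadratic in x (linear when s_i == s_j).  Returns the crossing
# where component i dominates on the left, or NA when no such crossing
# lies in the interval.
component_intersection <- function(ai, mi, si, aj, mj, sj) {
  if (ai <= 0 || aj <= 0) {
    return(NA_real_)
  }
  A <- 1 / sj^2 - 1 / si^2
  B <- 2 * (mi / si^2 - mj / sj^2)
  C <- mj^2 / sj^2 - mi^2 / si^2 + log(ai) - log(aj)
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) {
      return(NA_real_)
    }
    -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      return(NA_real_)
    }
    c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  }
  inside <- roots[roots > mi & roots < mj]
  if (length(inside) == 0L) {
    return(NA_real_)
  }
  gi <- function(x) ai * exp(-((x - mi) / si)^2)
  gj <- function(x) aj * exp(-((x - mj) / sj)^2)
  for (r in sort(inside)) {
    eps <- min(r - mi, mj - r) / 100
    if (gi(r - eps) >= gj(r - eps) && gj(r + eps) >= gi(r + eps)) {
      return(r)
    }
  }
  sort(inside)[[1L]]
}

#' Derive association thresholds from a tri-modal fit
#'
#' The cutoff between adjacent components `i` and `i + 1` is the score at
#' which the two weighted component curves intersect inside
#' `(mu_i, mu_{i+1})` (closed-form quadratic).  When any pair of adjacent
#' components has no crossing in the open interval (heavy overlap, or a
#' vanished amplitude), a fallback error of class `hgf_threshold_fallback`
#' is raised recommending [manual_thresholds()].
#'
#' @param fit An `hgf_trimodal_fit` or an `hgf_trimodal_params`.
#' @return An object of class `hgf_thresholds`: list with `cutoffs`
#'   (ascending numeric, length 2) and `source = "fitted"`.
#' @export
derive_thresholds <- function(fit) {
  params <- if (inherits(fit, "hgf_trimodal_fit")) fit$params else fit
  stopifnot(inherits(params, "hgf_trimodal_params"))
  if (any(diff(params$mu) <= 0)) {
    hgf_stop("peak centers must be strictly increasing", "hgf_invalid_input")
  }
  cutoffs <- vapply(1:2, function(i) {
    component_intersection(
      params$alpha[[i]], params$mu[[i]], params$sigma[[i]],
      params$alpha[[i + 1L]], params$mu[[i + 1L]], params$sigma[[i + 1L]]
    )
  }, numeric(1))
  if (any(is.na(cutoffs)) || any(diff(cutoffs) <= 0)) {
    hgf_stop(
      paste(
        "no component crossing between adjacent peaks (heavy overlap);",
        "supply manual_thresholds() instead"
      ),
      "hgf_threshold_fallback"
    )
  }
  new_thresholds(cutoffs, "fitted")
}

new_thresholds <- function(cutoffs, source) {
  cutoffs <- as.numeric(cutoffs)
  if (!length(cutoffs) %in% c(2L, 3L)) {
    hgf_stop("thresholds need 2 cutoffs (three bands) or 3 (four bands)", "hgf_invalid_input")
  }
  if (any(diff(cutoffs) <= 0)) {
    hgf_stop("cutoffs must be strictly ascending", "hgf_invalid_input")
  }
  if (any(cutoffs <= -1 | cutoffs >= 1)) {
    hgf_stop("cutoffs must lie strictly inside (-1, 1)", "hgf_invalid_input")
  }
  structure(list(cutoffs = cutoffs, source = source), class = "hgf_thresholds")
}

#' Manually specified association thresholds
#'
#' Two cutoffs give the three standard bands (unknown / potential /
#' established); three cutoffs insert an extra "low" band between unknown
#' and potential.
#'
#' @param cutoffs Strictly ascending numeric vector of length 2 or 3,
#'   each cutoff inside `(-1, 1)`.
#' @return An `hgf_thresholds` with `source = "manual"`.
#' @export
#' @examples
#' manual_thresholds(c(0.1, 0.3)) # ischemic-stroke style bands
#' manual_thresholds(c(0.05, 0.1, 0.2)) # four-band variant
manual_thresholds <- function(cutoffs) {
  new_thresholds(cutoffs, "manual")
}

#' @export
print.hgf_thresholds <- function(x, ...) {
  cat("<hgf thresholds> (", x$source, "): ",
    paste(format(x$cutoffs, digits = 4), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Partition ranked factors into association bands
#'
#' Band boundaries are left-closed, right-open: a score equal to a cutoff
#' belongs to the band above it; the top band is closed at +1.  With two
#' cutoffs the bands are unknown / potential / established; a third cutoff
#' inserts a "low" band between unknown and potential.  `NA` scores
#' (degenerate factor vectors) land in the unknown band.
#'
#' @param result An `hgf_query_result` (or any data frame with `factor`
#'   and `score` columns, or a named numeric vector of scores).
#' @param thresholds An `hgf_thresholds`.
#' @return An object of class `hgf_association_categories`: list with the
#'   band membership sets (`established`, `potential`, optionally `low`,
#'   `unknown`), the `thresholds`, and a `table` data frame
#'   (factor, score, band).
#' @export
categorize <- function(result, thresholds) {
  stopifnot(inherits(thresholds, "hgf_thresholds"))
  if (is.numeric(result) && !is.null(names(result))) {
    result <- data.frame(factor = names(result), score = unname(result), stringsAsFactors = FALSE)
  }
  if (!all(c("factor", "score") %in% names(result))) {
    hgf_stop("result must have 'factor' and 'score' columns", "hgf_invalid_input")
  }
  cutoffs <- thresholds$cutoffs
  bands <- if (length(cutoffs) == 2L) {
    c("unknown", "potential", "established")
  } else {
    c("unknown", "low", "potential", "established")
  }
  idx <- findInterval(result$score, cutoffs) + 1L
  idx[is.na(result$score)] <- 1L
  band <- bands[idx]
  tab <- data.frame(
    factor = result$factor, score = result$score, band = band,
    stringsAsFactors = FALSE
  )
  out <- list(
    established = tab$factor[tab$band == "established"],
    potential = tab$factor[tab$band == "potential"],
    unknown = tab$factor[tab$band == "unknown"],
    thresholds = thresholds,
    table = tab
  )
  if (length(cutoffs) == 3L) out$low <- tab$factor[tab$band == "low"]
  structure(out, class = "hgf_association_categories")
}

#' @export
print.hgf_association_categories <- function(x, ...) {
  cat("<hgf association bands>\n")
  cat("  established: ", length(x$established), "\n", sep = "")
  cat("  potential:   ", length(x$potential), "\n", sep = "")
  if (!is.null(x$low)) cat("  low:         ", length(x$low), "\n", sep = "")
  cat("  unknown:     ", length(x$unknown), "\n", sep = "")
  print(x$thresholds)
  invisible(x)
}
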