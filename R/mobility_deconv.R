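# Mobilogram deconvolution: constant baseline plus a sum of Gaussians
# parameterised by centre x_c, full width at half height w, and area A.

#' Gaussian component in FWHM-area form
#'
#' `g(x) = A * (2 sqrt(ln 2 / pi) / w) * exp(-4 ln 2 (x - x_c)^2 / w^2)`,
#' so that `w` is the full width at half height and `A` the area.
#'
#' @param x Drift times (ms).
#' @param x_c Centre (ms).
#' @param w FWHM (ms).
#' @param A Area (counts * ms).
#' @return Intensities at `x`.
#' @export
gaussian_fwhm <- function(x, x_c, w, A) {
  A * (2 * sqrt(log(2) / pi) / w) * exp(-4 * log(2) * (x - x_c)^2 / w^2)
}

#' Construct a mobilogram
#'
#' @param drift_time Strictly increasing drift-time axis (ms), >= 8 samples.
#' @param intensity Non-negative finite intensities, same length.
#' @param channel Label of the m/z channel (free-form, e.g. "m/z 2166, wh 7").
#' @return Object of class `mobilogram`.
#' @export
mobilogram <- function(drift_time, intensity, channel = "") {
  if (length(drift_time) < 8L) stop("mobilogram needs >= 8 samples")
  if (length(intensity) != length(drift_time)) stop("axis/intensity length mismatch")
  if (any(diff(drift_time) <= 0)) stop("drift_time must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  structure(list(drift_time = as.numeric(drift_time),
                 intensity = as.numeric(intensity),
                 channel = channel),
            class = "mobilogram")
}

# evaluate k_im + sum of Gaussians from a packed parameter vector
# theta = (k, x_c1, w1, A1, x_c2, w2, A2, ...)
.fim_eval <- function(theta, x) {
  y <- rep(theta[1], length(x))
  ncomp <- (length(theta) - 1L) / 3L
  for (j in seq_len(ncomp)) {
    p <- theta[1L + 3L * (j - 1L) + 1:3]
    y <- y + gaussian_fwhm(x, p[1], p[2], p[3])
  }
  y
}

# deterministic initial guesses by greedy residual subtraction: place each
# component at the maximum of the smoothed residual, subtract it, repeat.
# Finds shoulder peaks that are not local maxima; ties resolved by earlier
# drift time (which.max takes the first index).
.init_components <- function(x, y, n_components) {
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  k0 <- max(0, stats::quantile(ys, 0.1, names = FALSE))
  # width estimate from the tallest peak's half-height span
  apex <- which.max(ys)
  half <- k0 + (ys[apex] - k0) / 2
  lo <- apex; while (lo > 1L && ys[lo] > half) lo <- lo - 1L
  hi <- apex; while (hi < length(x) && ys[hi] > half) hi <- hi + 1L
  w_est <- max(x[hi] - x[lo], 4 * min(diff(x)))
  resid <- ys - k0
  centres <- h0 <- numeric(n_components)
  hfac <- 2 * sqrt(log(2) / pi)
  for (j in seq_len(n_components)) {
    i <- which.max(resid)
    centres[j] <- x[i]
    h0[j] <- max(resid[i], 1e-3 * max(ys))
    resid <- resid - gaussian_fwhm(x, x[i], w_est, h0[j] * w_est / hfac)
  }
  list(k = k0, x_c = centres, w = rep(w_est, n_components),
       A = h0 * w_est / hfac)
}

# apex height of each fitted component
.component_heights <- function(comp) {
  comp$A * (2 * sqrt(log(2) / pi)) / comp$w
}

.aicc <- function(rss, n, p) {
  if (n - p - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Fit a mobilogram to a baseline plus Gaussians
#'
#' Least-squares fit of `f_im(x) = k_im + sum_N g(x_c_N, w_N, A_N)` with
#' non-negativity bounds on the baseline, widths and areas. When
#' `n_components` is NULL the number of Gaussians is chosen by minimum
#' corrected AIC over 1..4 (subject to data support).
#'
#' @param mob A [mobilogram()].
#' @param n_components Number of Gaussians (1..6), or NULL to select by AICc.
#' @param init Optional list with vectors `x_c`, `w`, `A` and scalar `k`
#'   giving starting values; defaults to smoothed-local-maxima detection.
#' @param labels Optional character vector of species labels, one per
#'   component in drift-time order of the fitted centres.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence/stability tolerance on the residual sum of squares.
#' @param w_min Lower bound on component FWHM (ms); defaults to the larger of
#'   two samples and 1% of the axis span. Mobility peaks are
#'   instrument-broadened and never approach single-sample width; the bound
#'   keeps components from chasing isolated noise excursions.
#' @return Object of class `mobilogram_fit`: `k_im`, `components` (data.frame
#'   `x_c, w, A, label` sorted by `x_c`), `rss`, `converged`, `fitted`,
#'   `n_components`, `aicc`.
#' @export
fit_mobilogram <- function(mob, n_components = NULL, init = NULL, labels = NULL,
                           max_iter = 200L, tol = 1e-8, w_min = NULL) {
  stopifnot(inherits(mob, "mobilogram"))
  x <- mob$drift_time; y <- mob$intensity
  if (is.null(w_min)) w_min <- max(2 * min(diff(x)), diff(range(x)) / 100)
  if (is.null(n_components)) {
    fits <- list()
    for (nc in 1:4) {
      if (length(y) < 4 * (3 * nc + 1)) break
      fits[[nc]] <- fit_mobilogram(mob, nc, init = init, max_iter = max_iter,
                                   tol = tol, w_min = w_min)
    }
    if (length(fits) == 0L) stop("too few samples for even a single component")
    aiccs <- vapply(fits, function(f) f$aicc, 0)
    # a candidate is admissible only if it converged and every component's
    # apex rises at least 3 residual sigmas above zero: guards the AICc
    # comparison against noise-chasing components
    admissible <- vapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      sigma <- sqrt(f$rss / max(length(y) - (3 * i + 1), 1))
      f$converged && all(.component_heights(f$components) >= 3 * sigma)
    }, logical(1))
    pick <- if (any(admissible)) which(admissible)[which.min(aiccs[admissible])] else
      which.min(aiccs)
    best <- fits[[pick]]
    best$aicc_path <- aiccs
    if (!is.null(labels)) best <- .label_fit(best, labels)
    return(best)
  }
  if (n_components < 1 || n_components > 6) stop("n_components must be in 1..6")
  npar <- 3L * n_components + 1L
  if (length(y) < 4L * npar)
    stop(sprintf("insufficient data support: %d points for %d parameters (need >= %d)",
                 length(y), npar, 4L * npar))
  if (is.null(init)) init <- .init_components(x, y, n_components)
  if (any(init$x_c < min(x)) || any(init$x_c > max(x)))
    stop("data do not cover all initial centres")
  theta0 <- c(init$k, as.numeric(rbind(init$x_c, init$w, init$A)))
  # widths bounded below by w_min (narrower components would chase single
  # noisy points) and above by the axis span
  lower <- c(0, rep(c(min(x), w_min, 0), n_components))
  upper <- c(max(y), rep(c(max(x), diff(range(x)), Inf), n_components))
  theta0 <- pmin(pmax(theta0, lower), upper)
  resid_fn <- function(theta) y - .fim_eval(theta, x)
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol, ptol = tol)
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                       fn = resid_fn, control = ctl))
  theta <- fit$par
  rss <- sum(fit$fvec^2)
  converged <- fit$info %in% 1:4
  # honesty check: refitting from the solution must not improve the optimum
  refit <- suppressWarnings(
    minpack.lm::nls.lm(par = theta, lower = lower, upper = upper,
                       fn = resid_fn, control = ctl))
  if (sum(refit$fvec^2) < rss - tol * max(rss, 1)) {
    theta <- refit$par; rss <- sum(refit$fvec^2)
  }
  comp <- data.frame(
    x_c = theta[1L + 3L * (seq_len(n_components) - 1L) + 1L],
    w   = theta[1L + 3L * (seq_len(n_components) - 1L) + 2L],
    A   = theta[1L + 3L * (seq_len(n_components) - 1L) + 3L],
    label = NA_character_, stringsAsFactors = FALSE
  )
  comp <- comp[order(comp$x_c), , drop = FALSE]
  rownames(comp) <- NULL
  out <- structure(list(
    k_im = theta[1], components = comp, rss = rss, converged = converged,
    fitted = .fim_eval(theta, x), drift_time = x, intensity = y,
    channel = mob$channel, n_components = n_components,
    aicc = .aicc(rss, length(y), npar)
  ), class = "mobilogram_fit")
  if (!is.null(labels)) out <- .label_fit(out, labels)
  out
}

.label_fit <- function(fit, labels) {
  if (length(labels) != nrow(fit$components))
    stop("need one label per fitted component (drift-time order)")
  fit$components$label <- labels
  fit
}

#' @export
print.mobilogram_fit <- function(x, ...) {
  cat(sprintf("<mobilogram_fit> %s: %d component(s), k_im = %.3g, rss = %.4g, converged = %s\n",
              x$channel, nrow(x$components), x$k_im, x$rss, x$converged))
  print(x$components)
  invisible(x)
}

#' Relative contribution of each component to a channel
#'
#' Divides each component's area by the summed area of all components in the
#' fit: the relative population of each species within one charge-state
#' channel.
#'
#' @param fit A [fit_mobilogram()] result (must have converged).
#' @return Named numeric vector of fractions summing to 1 (names from
#'   component labels, or `comp1..compN`).
#' @export
relative_contributions <- function(fit) {
  stopifnot(inherits(fit, "mobilogram_fit"))
  if (!fit$converged) stop("fit did not converge; contributions not meaningful")
  A <- fit$components$A
  if (any(!is.finite(A))) stop("non-finite component areas")
  total <- sum(A)
  if (total <= 0) stop("total fitted area is zero")
  fr <- A / total
  nm <- fit$components$label
  if (any(is.na(nm))) nm <- paste0("comp", seq_along(A))
  stats::setNames(fr, nm)
}

#' Compare mobility-peak line widths between two groups of fits
#'
#' Pools the fitted FWHM values of the component labelled `species` across
#' replicate fits in each group and compares them by an unpaired two-tailed
#' Student's t-test. Used to contrast e.g. non-covalent against cross-linked
#' oligomers, whose reduced conformational dynamics narrow the mobility peak.
#'
#' @param fits_A,fits_B Lists of `mobilogram_fit` objects with labelled
#'   components.
#' @param species Component label to compare.
#' @return List: `mean_A`, `sd_A`, `mean_B`, `sd_B`, `t`, `df`, `p`,
#'   `widths_A`, `widths_B`.
#' @export
peak_width_stats <- function(fits_A, fits_B, species) {
  getw <- function(fits, grp) {
    w <- unlist(lapply(fits, function(f) {
      stopifnot(inherits(f, "mobilogram_fit"))
      f$components$w[f$components$label %in% species]
    }))
    if (length(w) < 2L)
      stop(sprintf("species '%s' present fewer than twice in group %s", species, grp))
    w
  }
  wA <- getw(fits_A, "A"); wB <- getw(fits_B, "B")
  tt <- stats::t.test(wA, wB, var.equal = TRUE, alternative = "two.sided")
  list(mean_A = mean(wA), sd_A = stats::sd(wA),
       mean_B = mean(wB), sd_B = stats::sd(wB),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       widths_A = wA, widths_B = wB)
}
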