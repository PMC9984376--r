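# Constrained bi-exponential lifetime fitting. Masked decay data are first
# summed over a spatial moving window and re-binned in time (256 -> 64 bins
# by default) to raise photon counts per decay, then each masked pixel's
# decay is fit by bounded nonlinear least squares to
#   F(t) = A * [ IRF (x) m(t) ],   m(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)
# with a1 + a2 = 1 (by parameterization), 0 <= a_i <= 1 and
# 0.02 <= tau_i <= 100 ns (box constraints), multi-start from random initial
# guesses. The amplitude A is profiled out analytically (variable
# projection), so the nonlinear search runs over (a1, tau1, tau2) only.

#' Fitting configuration for the lifetime stage
#'
#' @param n_restarts random multi-start initial guesses per pixel.
#' @param tau_min,tau_max lifetime box constraints in nanoseconds.
#' @param tau_init_range range (ns) of the log-uniform random initial
#'   lifetimes.
#' @param ftol relative residual-change convergence tolerance.
#' @param max_iter maximum optimizer iterations per start.
#' @param model_grid `"native"` evaluates the model and convolution on the
#'   IRF's native temporal grid and then applies the same temporal binning as
#'   the data (exact discretization match); `"binned"` evaluates directly on
#'   the coarse grid with a re-binned IRF.
#' @param weighting `"none"` for unweighted least squares (default) or
#'   `"poisson"` for inverse-variance weights `1 / max(I, 1)`.
#' @param wrap model steady-state incomplete decay (off by default).
#' @param fit_shift reserved flag for fitting a temporal IRF shift (not
#'   fitted by default; the simulated and measured grids are assumed
#'   aligned).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 5L, tau_min = 0.02, tau_max = 100,
                       tau_init_range = c(0.1, 10), ftol = 1e-8,
                       max_iter = 500L,
                       model_grid = c("native", "binned"),
                       weighting = c("none", "poisson"),
                       wrap = FALSE, fit_shift = FALSE) {
  structure(list(n_restarts = as.integer(n_restarts), tau_min = tau_min,
                 tau_max = tau_max, tau_init_range = tau_init_range,
                 ftol = ftol, max_iter = as.integer(max_iter),
                 model_grid = match.arg(model_grid),
                 weighting = match.arg(weighting), wrap = wrap,
                 fit_shift = fit_shift),
            class = "fit_config")
}

#' Spatially and temporally bin a masked decay image
#'
#' For every masked pixel, sums the decays of all masked pixels inside a
#' `window` x `window` moving window centered on that pixel (stride 1,
#' clipped at the image border), then merges consecutive temporal bins so
#' that `T` original bins become `t_out`. Unmasked pixels carry no output.
#' Implemented with summed-area tables, so cost is linear in image size per
#' temporal bin.
#'
#' @param decay a [decay_image()].
#' @param mask a [binary_mask()] (or logical matrix) matching the decay.
#' @param window spatial window side length in pixels (default 20).
#' @param t_out number of output temporal bins; must divide `T`.
#' @return A list of class `binned_decay` with `counts` (`[row, col, t_out]`,
#'   zero outside the mask), `mask`, `window`, `bin_width_ps` (coarse grid),
#'   `native_bin_width_ps`, `group` (bins merged per output bin), `period_ns`,
#'   `pixel_size_um`, `channel`.
#' @export
spatial_temporal_bin <- function(decay, mask, window = 20L, t_out = 64L) {
  stopifnot(inherits(decay, "decay_image"))
  mv <- if (inherits(mask, "binary_mask")) mask$values else mask
  d <- dim(decay$counts)
  if (!all(dim(mv) == d[1:2]))
    abort("mask shape does not match the decay image", "spheroflim_invalid_argument")
  if (window < 1L)
    abort("window must be >= 1", "spheroflim_invalid_argument")
  if (d[3] %% t_out != 0L)
    abort("t_out must divide the number of temporal bins", "spheroflim_invalid_argument")
  group <- d[3] %/% t_out
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo

  box_sum <- function(a) {        # windowed sum with border clipping
    n <- nrow(a); m <- ncol(a)
    cs <- apply(rbind(0, a), 2, cumsum)
    lo <- pmax(seq_len(n) - half_lo, 1L)
    hi <- pmin(seq_len(n) + half_hi, n)
    a2 <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    cs2 <- t(apply(cbind(0, a2), 1, cumsum))
    lo2 <- pmax(seq_len(m) - half_lo, 1L)
    hi2 <- pmin(seq_len(m) + half_hi, m)
    cs2[, hi2 + 1L, drop = FALSE] - cs2[, lo2, drop = FALSE]
  }

  out <- array(0, dim = c(d[1], d[2], t_out))
  n_px <- d[1] * d[2]
  mnum <- mv * 1
  for (k in seq_len(t_out)) {
    sl <- matrix(0, d[1], d[2])
    for (g in seq_len(group)) {
      kk <- (k - 1L) * group + g
      sl <- sl + decay$counts[, , kk]
    }
    bs <- box_sum(sl * mnum)
    bs[!mv] <- 0
    out[, , k] <- bs
  }
  structure(list(counts = out, mask = mv, window = as.integer(window),
                 bin_width_ps = decay$bin_width_ps * group,
                 native_bin_width_ps = decay$bin_width_ps,
                 group = group, period_ns = decay$period_ns,
                 pixel_size_um = decay$pixel_size_um,
                 channel = decay$channel),
            class = "binned_decay")
}

#' @export
print.binned_decay <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<binned_decay> %s %dx%d px, %d bins (window %d, group %d)\n",
              x$channel, d[1], d[2], d[3], x$window, x$group))
  invisible(x)
}

# internal: model machinery shared by fit_decay / fit_image. Builds the
# convolution operator once; returns a function (a1, tau1, tau2) -> predicted
# unit-amplitude decay shape on the coarse grid.
make_decay_predictor <- function(irf, n_out, period_ns, config) {
  n_native <- length(irf$values)
  if (config$model_grid == "native" && n_native %% n_out == 0L) {
    group <- n_native %/% n_out
    bw_ns <- period_ns / n_native
    gidx <- rep(seq_len(n_out), each = group)
    # fold the temporal grouping into the convolution operator up front:
    # rowsum(C %*% m) == (rowsum(C)) %*% m
    Cb <- rowsum(conv_operator(irf$values, n_native), gidx)
    function(a1, tau1, tau2) {
      m <- decay_model(a1, tau1, tau2, n_native, bw_ns,
                       period_ns = period_ns, wrap = config$wrap)
      as.vector(Cb %*% m)
    }
  } else {
    # coarse grid: re-bin the IRF exactly as the data
    if (n_native %% n_out == 0L) {
      group <- n_native %/% n_out
      v <- as.vector(rowsum(irf$values, rep(seq_len(n_out), each = group)))
    } else if (n_native == n_out) {
      v <- irf$values
    } else {
      abort("IRF length must equal or be a multiple of the decay length",
            "spheroflim_invalid_argument")
    }
    v <- v / sum(v)
    C <- conv_operator(v, n_out)
    bw_ns <- period_ns / n_out
    function(a1, tau1, tau2) {
      m <- decay_model(a1, tau1, tau2, n_out, bw_ns,
                       period_ns = period_ns, wrap = config$wrap)
      as.vector(C %*% m)
    }
  }
}

# internal: single bounded multi-start fit of one decay vector against a
# predictor closure; returns the fit_result list
fit_decay_core <- function(decay, predictor, config, seed) {
  w <- if (config$weighting == "poisson") 1 / pmax(decay, 1) else
    rep(1, length(decay))
  sw <- sqrt(w)
  ssr_and_A <- function(p) {
    s <- predictor(p[1], p[2], p[3])
    A <- sum(w * decay * s) / sum(w * s * s)
    if (!is.finite(A)) A <- 0
    A <- max(A, 0)
    r <- sw * (decay - A * s)
    list(r = r, A = A)
  }
  resid_fn <- function(p) ssr_and_A(p)$r
  lower <- c(0, config$tau_min, config$tau_min)
  upper <- c(1, config$tau_max, config$tau_max)
  set.seed(seed)
  best <- NULL
  for (k in seq_len(config$n_restarts)) {
    a0 <- runif(1)
    taus <- sort(exp(runif(2, log(config$tau_init_range[1]),
                           log(config$tau_init_range[2]))))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, taus[1], taus[2]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$ftol, maxiter = config$max_iter)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    dev <- fit$deviance
    if (is.null(best) || dev < best$deviance) best <- fit
  }
  if (is.null(best))
    abort("all fit restarts failed", "spheroflim_fit_failure")
  p <- best$par
  extra <- ssr_and_A(p)
  a1 <- p[1]; tau1 <- p[2]; tau2 <- p[3]
  if (tau1 > tau2) {            # enforce the fast/slow labelling convention
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    a1 <- 1 - a1
  }
  a2 <- 1 - a1
  converged <- best$info %in% 1:3
  list(alpha1 = a1, alpha2 = a2, tau1 = tau1, tau2 = tau2,
       amplitude = extra$A, residual_norm = best$deviance,
       converged = converged,
       tau1_identifiable = a1 > 0.01 && abs(tau2 - tau1) > 1e-6,
       tau2_identifiable = a2 > 0.01 && abs(tau2 - tau1) > 1e-6)
}

#' Fit the IRF-convolved bi-exponential model to one decay
#'
#' Minimizes `sum_t (I(t) - A * [IRF (x) m(t)])^2` over
#' `(alpha1, tau1, tau2)` with the amplitude `A` profiled analytically,
#' under the box constraints `0 <= alpha1 <= 1`,
#' `tau_min <= tau_i <= tau_max`. Runs `n_restarts` random initial guesses
#' and keeps the best residual; lifetimes are relabelled so
#' `tau1 <= tau2` (fast/slow convention).
#'
#' When one component carries (almost) no amplitude its lifetime is
#' unidentifiable; the result flags this via `tau1_identifiable` /
#' `tau2_identifiable` rather than erroring.
#'
#' @param decay numeric vector of (binned) photon counts.
#' @param irf an [irf_profile()]; its length must equal the decay length or
#'   an integer multiple of it (native-grid fitting, see [fit_config()]).
#' @param period_ns repetition period in nanoseconds spanning the native
#'   temporal window.
#' @param config a [fit_config()].
#' @param seed integer seed for the random restarts.
#' @return A list of class `fit_result`: `alpha1`, `alpha2` (summing to 1
#'   exactly), `tau1`, `tau2` (ns, `tau1 <= tau2`), `amplitude`,
#'   `residual_norm`, `converged`, identifiability flags.
#' @export
fit_decay <- function(decay, irf, period_ns = 12.5, config = fit_config(),
                      seed = 1L) {
  decay <- as.numeric(decay)
  if (all(decay == 0))
    abort("decay has no signal", "spheroflim_no_signal")
  predictor <- make_decay_predictor(irf, length(decay), period_ns, config)
  out <- fit_decay_core(decay, predictor, config, seed)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> a1 = %.3f, a2 = %.3f, tau1 = %.3f ns, tau2 = %.3f ns (SSR %.4g%s)\n",
    x$alpha1, x$alpha2, x$tau1, x$tau2, x$residual_norm,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Fit lifetime maps for a whole binned decay image
#'
#' Applies [fit_decay()] independently at every masked pixel (optionally on
#' a stride-subsampled grid for speed). Per-pixel random-restart seeds are
#' derived deterministically from the global seed and the pixel's linear
#' index, so results do not depend on evaluation order.
#'
#' @param binned a [spatial_temporal_bin()] result.
#' @param irf an [irf_profile()] on the native temporal grid.
#' @param config a [fit_config()].
#' @param seed global integer seed.
#' @param stride fit every `stride`-th row/column of the masked region
#'   (default 1 = every masked pixel); unfitted pixels are left out of the
#'   output mask.
#' @return A list of class `lifetime_maps` with per-pixel matrices `alpha1`,
#'   `alpha2`, `tau1`, `tau2`, `residual` (NA outside the fitted mask),
#'   logical `mask` of fitted pixels, `channel`, `pixel_size_um`, and
#'   `n_no_signal` (count of masked pixels skipped for lack of photons).
#' @export
fit_image <- function(binned, irf, config = fit_config(), seed = 1L,
                      stride = 1L) {
  stopifnot(inherits(binned, "binned_decay"))
  d <- dim(binned$counts)
  sel <- binned$mask
  if (stride > 1L) {
    keep_r <- ((seq_len(d[1]) - 1L) %% stride) == 0L
    keep_c <- ((seq_len(d[2]) - 1L) %% stride) == 0L
    sel <- sel & outer(keep_r, keep_c)
  }
  idx <- which(sel)
  maps <- list(alpha1 = matrix(NA_real_, d[1], d[2]),
               alpha2 = matrix(NA_real_, d[1], d[2]),
               tau1 = matrix(NA_real_, d[1], d[2]),
               tau2 = matrix(NA_real_, d[1], d[2]),
               residual = matrix(NA_real_, d[1], d[2]))
  fitted_mask <- matrix(FALSE, d[1], d[2])
  n_no_signal <- 0L
  n_px <- d[1] * d[2]
  predictor <- make_decay_predictor(irf, d[3], binned$period_ns, config)
  for (i in idx) {
    y <- binned$counts[i + (seq_len(d[3]) - 1L) * n_px]
    if (all(y == 0)) { n_no_signal <- n_no_signal + 1L; next }
    fr <- fit_decay_core(y, predictor, config, derive_seed(seed, i))
    maps$alpha1[i] <- fr$alpha1
    maps$alpha2[i] <- fr$alpha2
    maps$tau1[i] <- fr$tau1
    maps$tau2[i] <- fr$tau2
    maps$residual[i] <- fr$residual_norm
    fitted_mask[i] <- TRUE
  }
  structure(c(maps, list(mask = fitted_mask, channel = binned$channel,
                         pixel_size_um = binned$pixel_size_um,
                         n_no_signal = n_no_signal)),
            class = "lifetime_maps")
}
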