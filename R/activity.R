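#' Remove illumination-event frames from a time course
#'
#' Frames recorded during a light pulse carry broadband stray-light
#' artifacts and must not enter the rate regression. A frame is dropped
#' when (a) it is flagged in the `illuminated` mask, or (b) it is a
#' detected spike: its A672 deviates from the mean of its two neighbours
#' by more than `jump_au` (end frames are compared to their single
#' neighbour).
#'
#' @param tc A [time_course].
#' @param jump_au Artifact detection threshold in AU. Default 0.1.
#' @return The filtered [time_course] (time axis preserved).
#' @export
filter_illumination_events <- function(tc, jump_au = 0.1) {
  stopifnot(inherits(tc, "time_course"))
  n <- length(tc$time_s)
  a <- tc$a672
  # deviation from a running median: isolated artifact frames stand out
  # without dragging their clean neighbours over the threshold
  ref <- if (n >= 5) stats::runmed(a, 5, endrule = "median") else a
  spike <- abs(a - ref) > jump_au
  keep <- !(tc$illuminated | spike)
  if (!any(keep)) stop("all frames removed by illumination-event filter")
  time_course(tc$time_s[keep], a[keep], tc$illuminated[keep],
              tc$light_s[keep],
              if (!is.null(tc$spectra)) tc$spectra[keep])
}

#' Initial reaction rate from a product time course
#'
#' Ordinary least-squares slope of A672 over the longest initial window
#' of the trace that is still linear, scanning prefixes from the full
#' trace downwards. A prefix qualifies when its coefficient of
#' determination reaches `r2_min` *or* it shows no statistically
#' significant curvature (quadratic-term t statistic below 3) -- the
#' second criterion keeps noise-limited but genuinely linear traces,
#' whose raw R-squared is bounded by the signal-to-noise ratio, from
#' being rejected. The accepted window is then trimmed from the tail
#' while the last point's residual exceeds 3 times the RMSE of the rest,
#' so the onset of substrate depletion does not dilute the slope. The
#' slope is reported per minute of illumination (the `light_s` axis),
#' which for an enzyme that only turns over under light is the initial
#' reaction velocity.
#'
#' @param tc A [time_course], already filtered.
#' @param min_points Minimum number of distinct time points in the
#'   regression window. Default 4.
#' @param r2_min R-squared threshold for the linear prefix. Default 0.99.
#' @param axis `"light"` (default) regresses against cumulative
#'   illumination minutes; `"elapsed"` against elapsed minutes.
#' @return List of class `"activity_rate"`: `slope_au_per_min`,
#'   `r_squared`, `window` (frame indices used), `fallback` (TRUE when no
#'   prefix qualified and the shortest admissible window was used).
#' @export
initial_rate <- function(tc, min_points = 4, r2_min = 0.99,
                         axis = c("light", "elapsed")) {
  stopifnot(inherits(tc, "time_course"))
  axis <- match.arg(axis)
  x <- (if (axis == "light") tc$light_s else tc$time_s) / 60
  y <- tc$a672
  n <- length(x)
  n_distinct <- cumsum(!duplicated(x))
  k_min <- match(min_points, n_distinct)
  if (is.na(k_min)) stop("fewer than min_points distinct time points after filtering")
  fit_win <- function(k) {
    xi <- x[1:k]; yi <- y[1:k]
    b <- stats::cov(xi, yi) / stats::var(xi)
    a <- mean(yi) - b * mean(xi)
    resid <- yi - a - b * xi
    ss_res <- sum(resid^2)
    ss_tot <- sum((yi - mean(yi))^2)
    r2 <- if (ss_tot < .Machine$double.eps * max(1, mean(yi)^2) * k)
      1 else 1 - ss_res / ss_tot
    # t statistic of an added quadratic term (0 when it cannot improve)
    tq <- 0
    if (n_distinct[k] >= 4L && ss_res > 0) {
      X <- cbind(1, xi, xi^2)
      qf <- stats::lm.fit(X, yi)
      s2 <- sum(qf$residuals^2) / (k - 3)
      XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
      curv <- abs(qf$coefficients[3]) * diff(range(xi))^2
      if (!is.null(XtXinv) && s2 > 1e-20 * max(1, mean(yi^2))) {
        tq <- abs(qf$coefficients[3]) / sqrt(s2 * XtXinv[3, 3])
      } else if (curv > 1e-9 * max(diff(range(yi)), 1e-12)) {
        tq <- Inf  # exactly quadratic, noiseless: curvature is real
      }
    }
    list(slope = b, r2 = r2, k = k, resid = resid, t_quad = tq)
  }
  for (k in seq(n, k_min)) {
    w <- fit_win(k)
    if (w$r2 >= r2_min || w$t_quad < 3) {
      # tail trim against the onset of saturation
      while (w$k > k_min) {
        rest <- sqrt(sum(w$resid[-w$k]^2) / max(w$k - 3, 1))
        if (abs(w$resid[w$k]) <= 3 * rest + 1e-12) break
        w <- fit_win(w$k - 1L)
      }
      return(structure(list(slope_au_per_min = w$slope, r_squared = w$r2,
                            window = 1:w$k, fallback = FALSE),
                       class = "activity_rate"))
    }
  }
  w <- fit_win(k_min)
  warning("no prefix window was acceptably linear; using the first ",
          min_points, " distinct time points")
  structure(list(slope_au_per_min = w$slope, r_squared = w$r2,
                 window = 1:k_min, fallback = TRUE),
            class = "activity_rate")
}

#' @export
print.activity_rate <- function(x, ...) {
  cat(sprintf("<activity_rate: %.4g AU/min over %d frames, R2 = %.4f%s>\n",
              x$slope_au_per_min, length(x$window), x$r_squared,
              if (x$fallback) ", fallback window" else ""))
  invisible(x)
}

#' Specific activity from an absorbance slope
#'
#' Converts an initial slope at the product band into specific activity.
#' One unit (U) is the amount of enzyme converting 1 umol substrate per
#' minute; via Beer-Lambert, `rate_uM_per_min = slope / (eps672 * path) * 1e6`,
#' then `U = rate_uM_per_min * volume_L` and `U/mg = U / enzyme_mass_mg`.
#'
#' @param slope_au_per_min Regression slope in AU/min.
#' @param eps672 Product molar extinction coefficient in M^-1 cm^-1.
#'   Default 69950 (chlorophyllide at 672 nm).
#' @param path_cm Optical path in cm. Default 1.
#' @param volume_ml Assay volume in mL. Default 1.
#' @param enzyme_mg Enzyme mass in mg, > 0.
#' @return List: `product_rate_uM_per_min`, `units`, `specific_u_per_mg`.
#' @examples
#' specific_activity(0.06995, enzyme_mg = 0.01)  # 1 uM/min -> 0.1 U/mg
#' @export
specific_activity <- function(slope_au_per_min, eps672 = 69950, path_cm = 1,
                              volume_ml = 1, enzyme_mg) {
  if (eps672 <= 0 || path_cm <= 0 || volume_ml <= 0)
    stop("assay conditions must be positive")
  if (missing(enzyme_mg) || enzyme_mg <= 0) stop("enzyme mass must be > 0")
  rate_uM <- slope_au_per_min / (eps672 * path_cm) * 1e6
  units <- rate_uM * volume_ml * 1e-3   # uM * L = umol
  list(product_rate_uM_per_min = rate_uM, units = units,
       specific_u_per_mg = units / enzyme_mg)
}

#' Activity optimum and 80 percent range of a condition profile
#'
#' Given activity measured over a condition (pH or temperature), returns
#' the optimum (argmax; ties resolved to the midpoint of the tied set)
#' and the total width of the region where the piecewise-linear
#' interpolant stays at or above `threshold` times the maximum (the
#' conventional 80 percent criterion). Profiles still above threshold at
#' a boundary are flagged as truncated, since the true range extends
#' beyond the measured span.
#'
#' @param condition Numeric condition values (>= 3, strictly increasing
#'   after sorting; sorted internally).
#' @param activity Activities (same units throughout; the result is
#'   invariant to positive rescaling), finite, >= 0.
#' @param threshold Fraction of the maximum. Default 0.8.
#' @return List of class `"optimum_profile"`: `optimum`, `range_width`,
#'   `segments` (matrix of above-threshold intervals), `truncated`,
#'   `flat` (TRUE when all activities are equal, in which case the range
#'   is the full span).
#' @export
optimum_and_range <- function(condition, activity, threshold = 0.8) {
  if (length(condition) < 3L) stop("need at least 3 condition points")
  if (length(condition) != length(activity)) stop("length mismatch")
  if (any(!is.finite(activity))) stop("non-finite activities")
  o <- order(condition)
  x <- condition[o]; y <- activity[o]
  if (any(duplicated(x))) stop("duplicate condition values")
  ymax <- max(y)
  at_max <- which(y == ymax)
  optimum <- mean(range(x[at_max]))
  lev <- threshold * ymax
  flat <- diff(range(y)) == 0
  # above-threshold intervals of the piecewise-linear interpolant
  segs <- list()
  open <- if (y[1] >= lev) x[1] else NA_real_
  for (i in seq_len(length(x) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]
    if ((y1 - lev) * (y2 - lev) < 0) {
      xc <- x[i] + (lev - y1) / (y2 - y1) * (x[i + 1L] - x[i])
      if (is.na(open)) open <- xc
      else { segs[[length(segs) + 1L]] <- c(open, xc); open <- NA_real_ }
    }
  }
  if (!is.na(open)) segs[[length(segs) + 1L]] <- c(open, x[length(x)])
  segs <- do.call(rbind, segs)
  width <- if (is.null(segs)) 0 else sum(segs[, 2] - segs[, 1])
  truncated <- y[1] >= lev || y[length(y)] >= lev
  structure(list(optimum = optimum, range_width = width, segments = segs,
                 threshold = threshold, truncated = truncated, flat = flat),
            class = "optimum_profile")
}

#' @export
print.optimum_profile <- function(x, ...) {
  cat(sprintf("<optimum_profile: optimum %.4g, %g%% range width %.4g%s%s>\n",
              x$optimum, 100 * x$threshold, x$range_width,
              if (x$truncated) ", truncated" else "",
              if (x$flat) ", flat" else ""))
  invisible(x)
}

#' Monovinyl/divinyl substrate preference
#'
#' Compares specific activities measured with the monovinyl and divinyl
#' substrate forms. The fold-difference is the larger over the smaller
#' activity, rounded half-up to one decimal; a preference is called only
#' when the fold-difference exceeds 1.5.
#'
#' @param act_mv,act_dv Specific activities (U/mg) with the MV and DV
#'   substrate, both > 0.
#' @return List: `fold` (rounded to one decimal), `preferred` (`"MV"`,
#'   `"DV"` or `"none"`).
#' @examples
#' mv_dv_preference(0.22, 0.65)  # fold 3.0, prefers DV
#' @export
mv_dv_preference <- function(act_mv, act_dv) {
  if (act_mv <= 0 || act_dv <= 0) stop("activities must be > 0")
  fold_raw <- max(act_mv, act_dv) / min(act_mv, act_dv)
  fold <- floor(fold_raw * 10 + 0.5) / 10   # round half-up, one decimal
  preferred <- if (fold_raw > 1.5) {
    if (act_mv > act_dv) "MV" else "DV"
  } else "none"
  list(fold = fold, preferred = preferred)
}

#' Whole-cell bacteriochlorophyll index
#'
#' Normalizes a whole-cell absorption spectrum to a cell density of
#' OD660 = 1 and reports the near-infrared pigment band as the
#' OD860/OD660 ratio, the standard in vivo index of bacteriochlorophyll
#' accumulation.
#'
#' @param spec A [spectrum] (kind `"whole_cell"`) covering 660 and
#'   860 nm; values at exactly 660/860 nm are obtained by linear
#'   interpolation.
#' @return List: `spectrum` (normalized), `od660`, `od860`,
#'   `od860_over_od660`.
#' @export
bchl_index <- function(spec) {
  stopifnot(is_spectrum(spec))
  rng <- range(spec$wavelength)
  if (rng[1] > 660 || rng[2] < 860)
    stop("spectrum must cover 660 and 860 nm")
  at <- stats::approx(spec$wavelength, spec$value, xout = c(660, 860))$y
  if (at[1] <= 0) stop("OD660 must be > 0 for normalization")
  list(spectrum = spectrum(spec$wavelength, spec$value / at[1],
                           kind = spec$kind, meta = spec$meta),
       od660 = at[1], od860 = at[2], od860_over_od660 = at[2] / at[1])
}
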