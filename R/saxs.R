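#' Read a three-column SAXS profile
#'
#' Plain-text `.dat` profile: columns q (inverse Angstrom), intensity and
#' optionally sigma; comment lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return List of class `"saxs_profile"`: `q`, `intensity`, `sigma`
#'   (NULL when absent).
#' @export
read_saxs_dat <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  saxs_profile(tab[[1]], tab[[2]], if (ncol(tab) >= 3) tab[[3]])
}

#' @rdname read_saxs_dat
#' @param q Momentum transfer in inverse Angstrom, strictly increasing,
#'   > 0.
#' @param intensity Scattering intensity, finite.
#' @param sigma Optional uncertainties.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (any(q <= 0)) stop("q must be > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (length(q) != length(intensity)) stop("length mismatch")
  if (any(!is.finite(intensity))) stop("non-finite intensities")
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "saxs_profile")
}

#' Molecular mass from the Porod volume
#'
#' For globular proteins the Porod volume in cubic Angstrom divided by
#' 1.7 approximates the molecular mass in Da.
#'
#' @param v_porod Porod volume in cubic Angstrom, > 0.
#' @return Mass in kDa.
#' @examples
#' mw_from_porod(68000)  # 40 kDa
#' @export
mw_from_porod <- function(v_porod) {
  if (any(v_porod <= 0)) stop("volume must be > 0")
  v_porod / 1.7 / 1000
}

#' Molecular mass from an ab initio model's excluded volume
#'
#' The excluded volume of an averaged, filtered dummy-atom model in
#' cubic Angstrom divided by 2 approximates the molecular mass in Da.
#'
#' @param v_excl Excluded volume in cubic Angstrom, > 0.
#' @return Mass in kDa.
#' @export
mw_from_excluded_volume <- function(v_excl) {
  if (any(v_excl <= 0)) stop("volume must be > 0")
  v_excl / 2 / 1000
}

#' Guinier radius of gyration
#'
#' Iterative Guinier analysis: fits `ln I = ln I0 - Rg^2 q^2 / 3` on the
#' low-q window, then shrinks or grows the window to the largest prefix
#' satisfying `q * Rg <= qrg_max` at the current estimate, and repeats to
#' a fixpoint. The window is then guarded against systematic curvature:
#' while a statistically significant quadratic term in `q^2` biases the
#' fitted slope by more than `curv_tol` (as happens for compact shapes
#' whose form factor departs from the Guinier law within `qrg_max`), the
#' window is shrunk, mirroring the quality-driven range selection of
#' automated Guinier tools. A systematic positive residual at the lowest
#' q (an upturn indicating aggregation) is flagged.
#'
#' @param profile A [saxs_profile] (or list with `q` and `intensity`).
#' @param qrg_max Upper validity limit of the Guinier window in q*Rg.
#'   Default 1.3, the convention for globular particles.
#' @param min_points Minimum window size. Default 5.
#' @param curv_tol Maximum tolerated relative slope bias from window
#'   curvature. Default 0.01.
#' @return List of class `"guinier_fit"`: `rg` (Angstrom), `i0`,
#'   `window` (indices used), `qrg_range`, `aggregated` (upturn flag).
#' @export
guinier_rg <- function(profile, qrg_max = 1.3, min_points = 5,
                       curv_tol = 0.01) {
  q <- profile$q; I <- profile$intensity
  pos <- I > 0
  usable <- if (all(pos)) length(q) else min(which(!pos)) - 1L
  if (usable < min_points)
    stop("intensities must be positive over the low-q region")
  q <- q[1:usable]; I <- I[1:usable]
  fit_idx <- function(m) {
    x <- q[1:m]^2; y <- log(I[1:m])
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    list(slope = b, i0 = exp(a))
  }
  m <- min(length(q), max(min_points, 10L))
  rg <- NA_real_
  for (iter in 1:50) {
    f <- fit_idx(m)
    if (f$slope >= 0) {
      m <- m - 1L
      if (m < min_points) stop("no valid Guinier window (non-decaying low-q intensity)")
      next
    }
    rg <- sqrt(-3 * f$slope)
    m_new <- max(min_points, sum(q * rg <= qrg_max))
    m_new <- min(m_new, length(q))
    if (m_new == m) break
    m <- m_new
  }
  # curvature guard: shrink while a significant q^4 term biases the slope
  repeat {
    if (m <= max(min_points, 7L)) break
    u <- q[1:m]^2; y <- log(I[1:m])
    X <- cbind(1, u, u^2)
    qf <- stats::lm.fit(X, y)
    co <- qf$coefficients
    s2 <- sum(qf$residuals^2) / (m - 3)
    se_c <- suppressWarnings(sqrt(s2 * chol2inv(chol(crossprod(X)))[3, 3]))
    slope_bias <- co[3] * stats::cov(u, u^2) / stats::var(u)
    if (is.finite(se_c) && abs(co[3]) > 2 * se_c &&
        is.finite(co[2]) && co[2] != 0 &&
        abs(slope_bias / co[2]) > curv_tol) {
      m <- m - max(1L, m %/% 10L)
    } else break
  }
  f <- fit_idx(m)
  if (f$slope >= 0) stop("no valid Guinier window")
  rg <- sqrt(-3 * f$slope)
  # aggregation: the apparent size grows toward zero angle, so the
  # low-q half of the window fits a distinctly larger Rg than the
  # high-q half
  aggregated <- FALSE
  if (m >= 6L) {
    half <- m %/% 2L
    xl <- q[1:half]^2; yl <- log(I[1:half])
    xh <- q[(half + 1L):m]^2; yh <- log(I[(half + 1L):m])
    sl <- stats::cov(xl, yl) / stats::var(xl)
    sh <- stats::cov(xh, yh) / stats::var(xh)
    if (sl < 0 && sh < 0)
      aggregated <- sqrt(-sl) > 1.15 * sqrt(-sh)
    else if (sl < 0 && sh >= 0)
      aggregated <- TRUE
  }
  structure(list(rg = rg, i0 = f$i0, window = 1:m,
                 qrg_range = range(q[1:m]) * rg, aggregated = aggregated),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit: Rg = %.4g A, I0 = %.4g, %d points, qRg <= %.3g%s>\n",
              x$rg, x$i0, length(x$window), x$qrg_range[2],
              if (x$aggregated) ", aggregation suspected" else ""))
  invisible(x)
}

# Average residue masses (Da) and water, standard values used by
# composition-based parameter calculators.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Composition-based extinction coefficient and molecular mass
#'
#' Molar extinction coefficient at 280 nm from the Trp/Tyr/cystine
#' composition (5500, 1490 and 125 M^-1 cm^-1 per residue/bridge) and
#' the average molecular mass as the sum of residue masses plus one
#' water.
#'
#' @param sequence One-letter amino-acid string (20-letter alphabet;
#'   case-insensitive).
#' @param cys One of `"reduced"` (default: cysteines contribute nothing)
#'   or `"cystine"` (all cysteine pairs form bridges at 125 M^-1 cm^-1
#'   each).
#' @return List: `eps280` (M^-1 cm^-1), `mw` (Da), `n_trp`, `n_tyr`,
#'   `n_cys`, `no_aromatic_absorbance` (TRUE when eps280 is 0).
#' @examples
#' protein_params("WY")  # eps280 = 6990
#' @export
protein_params <- function(sequence, cys = c("reduced", "cystine")) {
  cys <- match.arg(cys)
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad)) stop("unknown amino acid letter(s): ",
                        paste(unique(bad), collapse = ", "))
  nW <- sum(aa == "W"); nY <- sum(aa == "Y"); nC <- sum(aa == "C")
  eps <- 5500 * nW + 1490 * nY +
    if (cys == "cystine") 125 * (nC %/% 2L) else 0
  mw <- sum(RESIDUE_MASS[aa]) + WATER_MASS
  list(eps280 = eps, mw = unname(mw), n_trp = nW, n_tyr = nY, n_cys = nC,
       no_aromatic_absorbance = eps == 0)
}
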