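#' Simulation configuration
#'
#' Shared settings for every generator: RNG seed, additive Gaussian noise
#' level and wavelength grid. All generators draw from R's default
#' Mersenne-Twister stream seeded with `seed` and restore the caller's
#' RNG state on exit, so the same seed always yields the same data set
#' regardless of surrounding code.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd Additive Gaussian noise standard deviation (AU for
#'   absorbance generators, ratio units for DSF). Default 0.002 AU, a
#'   realistic benchtop UV-Vis noise floor.
#' @param grid Wavelength grid as `c(start, stop, step)` in nm. Default
#'   620-720 nm in 1 nm steps, the scan range of the product-band assay.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, noise_sd = 0.002, grid = c(620, 720, 1)) {
  if (length(grid) != 3L || grid[3] <= 0) stop("grid must be c(start, stop, step) with step > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd, grid = grid),
            class = "sim_config")
}

grid_wavelengths <- function(cfg) seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3])

# Evaluate code with a temporary seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gaussian absorption band model
#'
#' Pigment Q_y bands are modelled as Gaussians; the lineshape is not
#' critical for unmixing, only that free and bound species are spectrally
#' resolvable.
#'
#' @param center Band center in nm.
#' @param width Gaussian sigma in nm, > 0.
#' @param amplitude Molar peak amplitude in AU per uM over a 1 cm path
#'   (e.g. 0.03 AU/uM corresponds to a molar extinction coefficient of
#'   30,000 M^-1 cm^-1).
#' @return A list of class `"band_model"`.
#' @export
band_model <- function(center, width, amplitude) {
  if (width <= 0) stop("band width must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_model")
}

band_profile <- function(band, wl) {
  band$amplitude * exp(-0.5 * ((wl - band$center) / band$width)^2)
}

# Exact mass-action bound fraction, written as an equilibrium root-finder
# so the generator stays independent of the closed-form binding model it
# is used to test.
equilibrium_bound_fraction <- function(a_tot, b_tot, kd) {
  vapply(a_tot, function(a) {
    if (b_tot <= 0) stop("pigment concentration must be > 0")
    if (a == 0) return(0)
    if (kd == 0) return(min(a, b_tot) / b_tot)
    f <- function(ab) (a - ab) * (b_tot - ab) - kd * ab
    ab <- stats::uniroot(f, c(0, min(a, b_tot)), tol = 1e-14)$root
    ab / b_tot
  }, numeric(1))
}

#' Simulate a spectral binding titration
#'
#' Generates the absorbance matrix of a pigment-depletion titration: a
#' fixed pigment concentration against increasing apo-protein, with the
#' bound species red-shifted relative to the free pigment, a
#' lambda^-2 turbidity baseline that grows with protein concentration,
#' and additive Gaussian noise. The per-sample bound fraction is computed
#' with an exact mass-action equilibrium root-finder and returned as
#' ground truth.
#'
#' @param true_kd Dissociation constant in uM, > 0.
#' @param pigment_conc Fixed pigment concentration in uM. Default 2.
#' @param protein_concs Apo-protein concentrations in uM; must include 0
#'   (the zero-protein spectrum doubles as the free reference). Default
#'   0-200 uM in 5 uM steps.
#' @param free_band,bound_band [band_model]s of the free and bound Q_y
#'   bands. Defaults: free at 630 nm, bound red-shifted by +8 nm, both
#'   sigma 9 nm and 0.03 AU/uM.
#' @param scatter_a Scatter scale per sample (AU nm^2). Default scales
#'   linearly with protein concentration up to 1e4 at the highest
#'   concentration, mimicking turbidity from concentrated protein.
#' @param y0 Constant baseline offset in AU. Default 0.002.
#' @param cfg A [sim_config].
#' @return A [titration_series] with attribute `"truth"`: list with
#'   `kd`, `bound_fraction`, `free_spectrum`, `bound_spectrum`
#'   (noise-free 2 uM species spectra without scatter), `scatter_a`, `y0`.
#' @export
sim_titration <- function(true_kd, pigment_conc = 2,
                          protein_concs = seq(0, 200, by = 5),
                          free_band = band_model(630, 9, 0.030),
                          bound_band = band_model(638, 9, 0.030),
                          scatter_a = NULL, y0 = 0.002,
                          cfg = sim_config()) {
  if (true_kd <= 0) stop("true_kd must be > 0")
  if (any(protein_concs < 0)) stop("protein concentrations must be >= 0")
  if (!any(protein_concs == 0)) stop("protein_concs must include 0")
  wl <- grid_wavelengths(cfg)
  if (is.null(scatter_a))
    scatter_a <- 1e4 * protein_concs / max(protein_concs, 1)
  if (length(scatter_a) == 1L) scatter_a <- rep(scatter_a, length(protein_concs))
  if (length(scatter_a) != length(protein_concs))
    stop("scatter_a must be scalar or one value per sample")
  frac <- equilibrium_bound_fraction(protein_concs, pigment_conc, true_kd)
  free_spec <- pigment_conc * band_profile(free_band, wl)
  bound_spec <- pigment_conc * band_profile(bound_band, wl)
  spectra <- local_seed(cfg$seed, {
    lapply(seq_along(protein_concs), function(i) {
      v <- (1 - frac[i]) * free_spec + frac[i] * bound_spec +
        scatter_a[i] * wl^-2 + y0 +
        stats::rnorm(length(wl), 0, cfg$noise_sd)
      spectrum(wl, v, kind = "absorbance",
               meta = list(sample_id = sprintf("A%03d", i),
                           conc_uM = protein_concs[i]))
    })
  })
  ser <- titration_series(spectra, protein_concs, pigment_conc)
  attr(ser, "truth") <- list(
    kd = true_kd, bound_fraction = frac,
    free_spectrum = spectrum(wl, free_spec),
    bound_spectrum = spectrum(wl, bound_spec),
    scatter_a = scatter_a, y0 = y0)
  ser
}

#' Simulate a pulsed-illumination photoconversion time course
#'
#' Product absorbance at 672 nm sampled once per second during cycles of
#' `pulse_s` seconds of actinic light and `dark_s` seconds of darkness.
#' Product concentration grows linearly with cumulative illumination time
#' at `rate_uM_per_min` until a configurable fraction of the substrate is
#' converted, then stays flat. Frames overlapping a light pulse are
#' flagged and corrupted with a broadband stray-light offset, giving the
#' event filter something realistic to remove.
#'
#' @param rate_uM_per_min Product formation rate per minute of light,
#'   >= 0.
#' @param pulse_s,dark_s Illumination cycle in seconds. Defaults 1 and 11.
#' @param n_cycles Number of cycles. Default 30.
#' @param eps672 Product molar extinction coefficient at 672 nm in
#'   M^-1 cm^-1. Default 69950.
#' @param substrate_uM Initial substrate concentration in uM. Default 3.5.
#' @param max_conversion Fraction of substrate convertible before the
#'   trace saturates. Default 0.5.
#' @param artifact_au Broadband offset added to illuminated frames.
#'   Default 0.5 AU.
#' @param frame_s Sampling interval in seconds. Default 1.
#' @param cfg A [sim_config] (noise is `cfg$noise_sd` on A672).
#' @return A [time_course] with attribute `"truth"`: list with `rate`
#'   (uM/min of light), `slope_au_per_min` (initial slope versus
#'   illumination time), `sat_a672` and `product_uM` per frame.
#' @export
sim_photoconversion <- function(rate_uM_per_min, pulse_s = 1, dark_s = 11,
                                n_cycles = 30, eps672 = 69950,
                                substrate_uM = 3.5, max_conversion = 0.5,
                                artifact_au = 0.5, frame_s = 1,
                                cfg = sim_config()) {
  if (rate_uM_per_min < 0) stop("rate must be >= 0")
  period <- pulse_s + dark_s
  t <- seq(0, n_cycles * period, by = frame_s)
  phase <- t %% period
  lit <- phase < pulse_s
  # cumulative light seconds at time t
  light_s <- pmin(phase, pulse_s) + (t %/% period) * pulse_s
  product <- pmin(rate_uM_per_min * light_s / 60,
                  max_conversion * substrate_uM)
  a672 <- eps672 * product * 1e-6
  a672 <- local_seed(cfg$seed, {
    a672 + stats::rnorm(length(t), 0, cfg$noise_sd) +
      ifelse(lit, artifact_au, 0)
  })
  tc <- time_course(time_s = t, a672 = a672, illuminated = lit,
                    light_s = light_s)
  attr(tc, "truth") <- list(rate = rate_uM_per_min,
                            slope_au_per_min = rate_uM_per_min * eps672 * 1e-6,
                            sat_a672 = eps672 * max_conversion * substrate_uM * 1e-6,
                            product_uM = product)
  tc
}

#' Simulate a DSF thermal-unfolding trace
#'
#' Two-state unfolding read out as the F350/F330 fluorescence ratio: a
#' logistic sigmoid with its inflection exactly at `tm`, flat native and
#' unfolded baselines, and Gaussian noise on the 350 nm channel. The
#' 330 nm channel is a smooth positive reference so the ratio carries the
#' transition.
#'
#' @param tm Melting temperature in degrees C; must lie inside `temps`.
#' @param steepness Transition width parameter in degrees C (logistic
#'   scale). Default 2.5.
#' @param baselines Native and unfolded ratio levels `c(low, high)`.
#'   Default `c(0.80, 1.10)`.
#' @param temps Temperature grid in degrees C. Default 15-85 in 0.25
#'   steps (the instrument ramp is finer; this keeps simulated traces
#'   light while remaining well-resolved).
#' @param cfg A [sim_config]; `noise_sd` applies to the ratio.
#' @return A [dsf_trace] with attribute `"truth"` containing `tm`.
#' @export
sim_dsf <- function(tm, steepness = 2.5, baselines = c(0.80, 1.10),
                    temps = seq(15, 85, by = 0.25), cfg = sim_config()) {
  if (tm <= min(temps) || tm >= max(temps))
    stop("tm must lie strictly inside the temperature range")
  if (steepness <= 0) stop("steepness must be > 0")
  ratio <- baselines[1] + (baselines[2] - baselines[1]) /
    (1 + exp(-(temps - tm) / steepness))
  f330 <- 1e4 * (1 - 2e-3 * (temps - min(temps)))
  ratio_noisy <- local_seed(cfg$seed,
                            ratio + stats::rnorm(length(temps), 0, cfg$noise_sd))
  tr <- dsf_trace(temps, f330, ratio_noisy * f330)
  attr(tr, "truth") <- list(tm = tm, baselines = baselines)
  tr
}

#' Markers scanned in the phototrophy presence/absence analysis
#' @export
MARKER_SET <- c("LPOR", "BchB", "BchL", "BchN", "RuBisCO_large", "PRK",
                "BchE", "AcsF", "PufL", "PufM", "PsaA", "PsaB",
                "PsbA", "PsbD")

#' Simulate a marker presence/absence table
#'
#' Draws genomes from three archetypes: the aerobic anoxygenic
#' phototroph pattern (DPOR subunits + type II reaction center + at least
#' one oxidative cyclase, Calvin-cycle markers incomplete), an oxygenic
#' pattern (RuBisCO and PRK present together with photosystem genes), and
#' a non-phototroph pattern (no photosynthesis markers; occasionally a
#' lone RuBisCO). True class labels are retained.
#'
#' @param n_genomes Number of genomes.
#' @param class_mix Proportions `c(aapb, oxygenic, none)` summing to 1.
#'   Default `c(0.4, 0.3, 0.3)`.
#' @param cfg A [sim_config].
#' @return A logical `marker_matrix` (genomes x markers) with attribute
#'   `"truth"`: character vector of class labels.
#' @export
sim_marker_table <- function(n_genomes, class_mix = c(0.4, 0.3, 0.3),
                             cfg = sim_config()) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  classes <- c("aapb", "oxygenic", "none")
  local_seed(cfg$seed, {
    lab <- sample(classes, n_genomes, replace = TRUE, prob = class_mix)
    m <- matrix(FALSE, n_genomes, length(MARKER_SET),
                dimnames = list(sprintf("genome_%04d", seq_len(n_genomes)),
                                MARKER_SET))
    for (i in seq_len(n_genomes)) {
      row <- stats::setNames(rep(FALSE, length(MARKER_SET)), MARKER_SET)
      if (lab[i] == "aapb") {
        row[c("BchB", "BchL", "BchN", "PufL", "PufM")] <- TRUE
        cyc <- sample(c("AcsF", "BchE", "both"), 1)
        row[c("AcsF", "BchE")] <- switch(cyc,
          AcsF = c(TRUE, FALSE), BchE = c(FALSE, TRUE), both = c(TRUE, TRUE))
        # at most one Calvin marker, so the genome still lacks the pair
        calvin <- sample(c("none", "RuBisCO_large", "PRK"), 1,
                         prob = c(0.6, 0.2, 0.2))
        if (calvin != "none") row[calvin] <- TRUE
        row["LPOR"] <- stats::runif(1) < 0.5
      } else if (lab[i] == "oxygenic") {
        row[c("RuBisCO_large", "PRK", "PsaA", "PsaB", "PsbA", "PsbD",
              "LPOR", "AcsF")] <- TRUE
        row[c("BchB", "BchL", "BchN")] <- stats::runif(1) < 0.5
      } else {
        row["RuBisCO_large"] <- stats::runif(1) < 0.1
      }
      m[i, ] <- row
    }
    structure(m, class = c("marker_matrix", class(m)), truth = lab)
  })
}

#' Simulate a tree set with a clade at a chosen frequency
#'
#' Builds `n_trees` unrooted binary topologies over `taxa` such that
#' exactly `round(frequency * n_trees)` of them contain `clade` as a
#' monophyletic group; the remaining trees break the clade by swapping
#' one clade member with an outside leaf (re-drawn until the clade is
#' genuinely non-monophyletic).
#'
#' @param taxa Character vector of leaf labels (>= 4).
#' @param clade Character subset of `taxa`, size >= 2 and <=
#'   `length(taxa) - 2`.
#' @param frequency Target proportion of trees containing the clade.
#' @param n_trees Number of trees.
#' @param cfg A [sim_config].
#' @return A `multiPhylo` list of trees with attribute `"truth"`: logical
#'   vector marking the clade-containing trees.
#' @export
sim_tree_set <- function(taxa, clade, frequency, n_trees,
                         cfg = sim_config()) {
  if (length(clade) < 2L) stop("clade must contain at least 2 taxa")
  if (!all(clade %in% taxa)) stop("clade must be a subset of taxa")
  if (length(taxa) - length(clade) < 2L)
    stop("at least 2 taxa must lie outside the clade")
  if (frequency < 0 || frequency > 1) stop("frequency must be in [0, 1]")
  n_with <- round(frequency * n_trees)
  rest <- setdiff(taxa, clade)
  local_seed(cfg$seed, {
    make_with <- function() {
      # random backbone over outside taxa plus a placeholder leaf, then
      # graft a random subtree over the clade taxa in its place
      backbone <- ape::rtopology(length(rest) + 1L, rooted = FALSE,
                                 tip.label = sample(c(rest, ".CLADE.")))
      sub <- if (length(clade) == 2L) {
        ape::read.tree(text = sprintf("(%s,%s);", clade[1], clade[2]))
      } else {
        ape::rtopology(length(clade), rooted = TRUE,
                       tip.label = sample(clade))
      }
      where <- which(backbone$tip.label == ".CLADE.")
      tr <- ape::bind.tree(backbone, sub, where = where)
      ape::unroot(tr)
    }
    make_without <- function() {
      repeat {
        tr <- make_with()
        a <- sample(clade, 1); b <- sample(rest, 1)
        lab <- tr$tip.label
        lab[lab == a] <- ".SWAP."; lab[lab == b] <- a; lab[lab == ".SWAP."] <- b
        tr$tip.label <- lab
        if (!is_clade_monophyletic(tr, clade)) return(tr)
      }
    }
    has_clade <- sample(rep(c(TRUE, FALSE), c(n_with, n_trees - n_with)))
    trees <- lapply(has_clade, function(w) if (w) make_with() else make_without())
    class(trees) <- "multiPhylo"
    attr(trees, "truth") <- has_clade
    trees
  })
}
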