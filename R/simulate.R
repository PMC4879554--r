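# Synthetic Raman spectrum generator: Lorentzian bands with class-dependent
# amplitudes on a smooth polynomial baseline, additive Gaussian noise and
# lognormal batch-to-batch intensity scaling -- the minimal statistical
# structure the derivative/normalization preprocessing and PC-LDA chain are
# designed to cope with.

#' Simulation configuration
#'
#' @param n_per_group spectra per group, >= 2; default 30 (five to six
#'   acquisitions from each of several cell pellets is typical practice).
#' @param region region name or bounds, see [region_bounds()].
#' @param step native sampling step of the simulated axis in cm^-1; default 2,
#'   typical pixel spacing of a low-dispersion fibre-probe CCD system (the
#'   analysis pipeline later interpolates onto its own finer grid, which is
#'   why differentiation precedes interpolation).
#' @param baseline_coef polynomial coefficients (constant first, degree <= 5)
#'   of the smooth background, evaluated in the scaled coordinate
#'   u in [-1, 1] over the simulated range; amplitudes are in band units.
#' @param noise_sd additive Gaussian noise SD as a fraction of the largest
#'   band amplitude in the profile; default 0.05.
#' @param batch_scale_sd SD of the lognormal per-batch multiplicative
#'   intensity factor; default 0.1.
#' @param n_batches number of acquisition batches, default 3.
#' @param amp_cv default coefficient of variation of per-spectrum band
#'   amplitudes, default 0.05.
#' @param seed integer RNG seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 30L, region = "fingerprint", step = 2,
                       baseline_coef = c(2, 0.8, -0.5, 0.3, -0.1, 0.05),
                       noise_sd = 0.05, batch_scale_sd = 0.1, n_batches = 3L,
                       amp_cv = 0.05, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(baseline_coef) > 6) stop("baseline degree must be <= 5")
  structure(list(
    n_per_group = as.integer(n_per_group), region = region, step = step,
    baseline_coef = baseline_coef, noise_sd = noise_sd,
    batch_scale_sd = batch_scale_sd, n_batches = as.integer(n_batches),
    amp_cv = amp_cv, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Class band profile
#'
#' @param label class label.
#' @param bands data.frame with columns `center` (cm^-1), `width` (Lorentzian
#'   half-width at half-maximum, 3-40 cm^-1), `amp_mean` (>= 0) and
#'   optionally `amp_cv`.
#' @return list of class `band_profile`.
#' @export
band_profile <- function(label, bands) {
  stopifnot(all(c("center", "width", "amp_mean") %in% names(bands)))
  if (any(bands$width < 3) || any(bands$width > 40))
    stop("band widths must lie in [3, 40] cm^-1")
  if (any(bands$amp_mean < 0)) stop("band amplitudes must be >= 0")
  if (is.null(bands$amp_cv)) bands$amp_cv <- NA_real_
  structure(list(label = label, bands = bands), class = "band_profile")
}

# Shared cellular backbone: every class shows these bands; class presets
# shift a subset of amplitudes.
.backbone_bands <- function() {
  data.frame(
    center = c(1008, 1095, 1260, 1272, 1305, 1340, 1447, 1485, 1560, 1579,
               1610, 1660, 1725, 1746, 2850, 2880, 2900, 2930),
    width  = c(   6,    8,   10,    8,    8,    9,    8,    8,    8,    8,
                  7,   10,    8,    7,   15,   15,   15,   18),
    amp_mean = c(0.75, 0.45, 0.55, 0.30, 0.45, 0.50, 0.85, 0.30, 0.25, 0.25,
                 0.25, 1.00, 0.20, 0.20, 0.60, 0.50, 0.70, 0.60)
  )
}

.bump <- function(bands, centers, delta) {
  i <- match(centers, bands$center)
  bands$amp_mean[i] <- pmax(0, bands$amp_mean[i] + delta)
  bands
}

#' Packaged class band-profile presets
#'
#' Encodes the class-specific biochemical shifts the workflow is designed to
#' detect: parent cells elevated at DNA/protein bands (1008, 1095, 1340,
#' 1560, 1610, ~2900-2930 cm^-1); recurrent cells elevated at lipid and
#' ceramide bands (1272, 1305, 1447, 1660, 1673, 1725, 1746, 2840-2880);
#' non-responder tissue elevated at 1313, 1320, 1340, 1367, 1485, 1579 and
#' 1750 cm^-1 relative to responder tissue. The `sf268_recurrent` preset
#' inverts the DNA/protein shift (lower protein, slightly higher DNA), the
#' known exception among the recurrent lines.
#'
#' @param class one of `"parent"`, `"recurrent"`, `"sf268_recurrent"`,
#'   `"responder"`, `"non_responder"`.
#' @param delta amplitude shift applied to the class's elevated bands
#'   (arbitrary units), default 0.15.
#' @return a [band_profile()].
#' @export
profile_preset <- function(class = c("parent", "recurrent", "sf268_recurrent",
                                     "responder", "non_responder"),
                           delta = 0.15) {
  class <- match.arg(class)
  bands <- .backbone_bands()
  bands <- switch(class,
    parent = .bump(bands, c(1008, 1095, 1340, 1560, 1610, 2900, 2930), delta),
    recurrent = {
      b <- .bump(bands, c(1272, 1305, 1447, 1660, 1725, 1746, 2850, 2880),
                 delta)
      rbind(b, data.frame(center = 1673, width = 6, amp_mean = delta))
    },
    sf268_recurrent = {
      b <- .bump(bands, c(1095, 1340, 1610), delta / 2)
      .bump(b, c(1008, 1560, 2900, 2930), -delta / 2)
    },
    responder = bands,
    non_responder = {
      b <- rbind(bands,
                 data.frame(center = c(1313, 1320, 1367, 1750),
                            width = c(7, 7, 8, 7),
                            amp_mean = c(0, 0, 0, 0)))
      .bump(b, c(1313, 1320, 1340, 1367, 1485, 1579, 1750), delta)
    })
  band_profile(class, bands)
}

#' Two-class profile pair differing at a single band
#'
#' Convenience constructor for calibration studies: both classes share the
#' backbone; class `b` is elevated by `delta` at one band. With the default
#' `delta = NULL` the shift is 4 x the absolute additive-noise SD implied by
#' `cfg` (`cfg$noise_sd` x the largest backbone amplitude).
#'
#' @param cfg a [sim_config()].
#' @param band center of the differing band, default 1447 cm^-1.
#' @param delta amplitude shift; `NULL` for 4 x noise SD.
#' @return named list of two [band_profile()] objects, `a` and `b`.
#' @export
two_class_profiles <- function(cfg = sim_config(), band = 1447,
                               delta = NULL) {
  bands <- .backbone_bands()
  if (is.null(delta)) delta <- 4 * cfg$noise_sd * max(bands$amp_mean)
  list(a = band_profile("a", bands),
       b = band_profile("b", .bump(bands, band, delta)))
}

.eval_baseline <- function(coef, wn) {
  u <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  as.numeric(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

.lorentzians <- function(wn, centers, widths, amps) {
  y <- numeric(length(wn))
  for (i in seq_along(centers))
    y <- y + amps[i] * widths[i]^2 / ((wn - centers[i])^2 + widths[i]^2)
  y
}

#' Simulate one spectrum
#'
#' intensity(v) = batch_factor x [sum_i amp_i L(v; center_i, width_i)
#' + baseline(v)] + noise(v), with per-spectrum amplitudes drawn from the
#' profile's mean/CV (truncated at zero) and L a unit-height Lorentzian, so
#' with zero noise and CV the peak value of an isolated band equals its
#' amplitude. Consumes the current RNG stream; seed the study functions, or
#' `set.seed()`, for reproducibility.
#'
#' @param profile a [band_profile()].
#' @param cfg a [sim_config()].
#' @param batch_factor multiplicative batch intensity factor, default 1.
#' @param center_shift rigid band-position shift in cm^-1 (sample-specific
#'   jitter), default 0.
#' @param meta metadata list for the resulting spectrum.
#' @return a [raman_spectrum] on the region grid extended by a 20 cm^-1
#'   margin on each side (so derivative and interpolation stages have
#'   support).
#' @export
simulate_spectrum <- function(profile, cfg = sim_config(), batch_factor = 1,
                              center_shift = 0, meta = list()) {
  b <- region_bounds(cfg$region)
  wn <- seq(b[1] - 20, b[2] + 20, by = cfg$step)
  bands <- profile$bands
  in_range <- bands$center + center_shift > min(wn) &
    bands$center + center_shift < max(wn)
  if (!any(in_range))
    warning("profile has no bands inside the simulated region; ",
            "baseline + noise only")
  bands <- bands[in_range, , drop = FALSE]
  cv <- ifelse(is.na(bands$amp_cv), cfg$amp_cv, bands$amp_cv)
  amps <- pmax(0, stats::rnorm(nrow(bands), bands$amp_mean,
                               cv * bands$amp_mean))
  y <- .lorentzians(wn, bands$center + center_shift, bands$width, amps) +
    .eval_baseline(cfg$baseline_coef, wn)
  noise_abs <- cfg$noise_sd * max(profile$bands$amp_mean)
  y <- batch_factor * y + stats::rnorm(length(wn), 0, noise_abs)
  raman_spectrum(wn, y, meta = meta)
}

# One labelled group of spectra; batch factors supplied by the caller so
# batches can span groups.
.simulate_group <- function(profile, cfg, group, batch_factors,
                            center_shift = 0, id_prefix = group) {
  n <- cfg$n_per_group
  batch_idx <- rep(seq_along(batch_factors), length.out = n)
  lapply(seq_len(n), function(k) {
    simulate_spectrum(
      profile, cfg, batch_factor = batch_factors[batch_idx[k]],
      center_shift = center_shift,
      meta = list(
        spectrum_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", id_prefix), k),
        sample_id = id_prefix, group = group,
        batch = sprintf("b%d", batch_idx[k]),
        region = if (is.character(cfg$region)) cfg$region else "custom",
        seed = cfg$seed))
  })
}

#' Simulate a labelled multi-group spectrum set
#'
#' Workhorse behind the study generators: one group per profile, shared
#' batch structure, everything determined by `cfg$seed`.
#'
#' @param profiles named list of [band_profile()] objects; names become
#'   group labels.
#' @param cfg a [sim_config()].
#' @param center_jitter_sd if > 0, each group receives one rigid band-center
#'   shift drawn from Uniform(-j, j) (sample-specific peak-position
#'   variation), default 0.
#' @return a [raman_set] of raw (unprocessed) spectra.
#' @export
simulate_set <- function(profiles, cfg = sim_config(), center_jitter_sd = 0) {
  set.seed(cfg$seed)
  batch_factors <- stats::rlnorm(cfg$n_batches, 0, cfg$batch_scale_sd)
  spectra <- list()
  for (g in names(profiles)) {
    shift <- if (center_jitter_sd > 0)
      stats::runif(1, -center_jitter_sd, center_jitter_sd) else 0
    spectra <- c(spectra,
                 .simulate_group(profiles[[g]], cfg, g, batch_factors, shift))
  }
  raman_set(spectra)
}

#' Simulate the eight-group cell study
#'
#' Parent and recurrent populations of four cultures (PS1, PS2, SF268,
#' U87MG); recurrent groups use the lipid-elevated preset except SF268 whose
#' recurrent line inverts the DNA/protein shift. Each group carries a small
#' sample-specific band-center jitter (<= `center_jitter` cm^-1) and
#' per-group amplitude variation so the eight groups are distinct, as
#' between-sample biology would make them.
#'
#' @param cfg a [sim_config()]; `cfg$n_per_group` spectra per group.
#' @param delta class band-amplitude shift passed to [profile_preset()].
#' @param center_jitter maximum rigid band shift per group in cm^-1,
#'   default 3.
#' @return a [raman_set] of `8 * cfg$n_per_group` raw spectra with groups
#'   `"<culture> P"` / `"<culture> R"`.
#' @export
simulate_cell_study <- function(cfg = sim_config(), delta = 0.15,
                                center_jitter = 3) {
  set.seed(cfg$seed)
  cultures <- c("PS1", "PS2", "SF268", "U87MG")
  batch_factors <- stats::rlnorm(cfg$n_batches, 0, cfg$batch_scale_sd)
  spectra <- list()
  for (cu in cultures) {
    for (pop in c("P", "R")) {
      base <- if (pop == "P") profile_preset("parent", delta)
        else if (cu == "SF268") profile_preset("sf268_recurrent", delta)
        else profile_preset("recurrent", delta)
      # sample-specific variation: rigid center shift + per-band amplitude
      # lognormal wobble, one draw per group
      prof <- base
      prof$bands$amp_mean <- prof$bands$amp_mean *
        exp(stats::rnorm(nrow(prof$bands), 0, 0.05))
      shift <- stats::runif(1, -center_jitter, center_jitter)
      g <- paste(cu, pop)
      spectra <- c(spectra,
                   .simulate_group(prof, cfg, g, batch_factors, shift,
                                   id_prefix = paste0(cu, pop)))
    }
  }
  raman_set(spectra)
}

#' Simulate the responder / non-responder tissue study
#'
#' Two groups on the 1200-1800 cm^-1 tissue region, with a configurable
#' fraction of spectra drawn from a mixed (half-way) profile to mimic the
#' clonal-cell overlap between outcome groups.
#'
#' @param cfg a [sim_config()]; defaults to 45 spectra per class on the
#'   tissue region.
#' @param delta class band-amplitude shift, default 0.15.
#' @param overlap_fraction probability that a spectrum is drawn from the
#'   mixed profile while keeping its nominal label, default 0.1.
#' @return a [raman_set] with groups `"Responders"` / `"Non-responders"`.
#' @export
simulate_tissue_study <- function(cfg = sim_config(n_per_group = 45,
                                                   region = "tissue"),
                                  delta = 0.15, overlap_fraction = 0.1) {
  set.seed(cfg$seed)
  prof <- list("Responders" = profile_preset("responder", delta),
               "Non-responders" = profile_preset("non_responder", delta))
  centers <- sort(unique(c(prof[[1]]$bands$center, prof[[2]]$bands$center)))
  full <- function(p) {
    amp <- numeric(length(centers))
    wid <- numeric(length(centers))
    i <- match(p$bands$center, centers)
    amp[i] <- p$bands$amp_mean
    wid[i] <- p$bands$width
    list(amp = amp, wid = wid)
  }
  fa <- full(prof[[1]]); fb <- full(prof[[2]])
  wid <- ifelse(fa$wid > 0, fa$wid, fb$wid)
  mixed <- band_profile("mixed", data.frame(
    center = centers, width = wid, amp_mean = (fa$amp + fb$amp) / 2))
  batch_factors <- stats::rlnorm(cfg$n_batches, 0, cfg$batch_scale_sd)
  spectra <- list()
  for (g in names(prof)) {
    grp <- .simulate_group(prof[[g]], cfg, g, batch_factors,
                           id_prefix = gsub("[^A-Za-z]", "", g))
    mix <- stats::runif(length(grp)) < overlap_fraction
    for (k in which(mix)) {
      meta <- grp[[k]]$meta
      grp[[k]] <- simulate_spectrum(
        mixed, cfg,
        batch_factor = batch_factors[rep(seq_len(cfg$n_batches),
                                         length.out = length(grp))[k]],
        meta = meta)
    }
    spectra <- c(spectra, grp)
  }
  raman_set(spectra)
}

#' Simulate a clonogenic survival curve
#'
#' SF(D) = exp(-D / true_d0) x lognormal(0, noise_sd) at positive doses;
#' SF(0) is fixed at 1.
#'
#' @param true_d0 true D0 in Gy.
#' @param doses dose points in Gy, strictly increasing, including 0.
#' @param noise_sd lognormal noise SD on the log-survival scale,
#'   default 0.05.
#' @param seed optional RNG seed.
#' @return list with `doses` and `surviving_fraction`.
#' @export
simulate_survival <- function(true_d0, doses = c(0, 2, 4, 6, 8),
                              noise_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sf <- exp(-doses / true_d0) * stats::rlnorm(length(doses), 0, noise_sd)
  sf[doses == 0] <- 1
  list(doses = doses, surviving_fraction = sf)
}
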