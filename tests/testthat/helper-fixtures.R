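# Shared fixture builders: synthetic 1D profiles and small frames built
# in code, deterministic under fixed seeds.

# radial profile: Gaussian peak(s) on an exponential background, optional
# Poisson noise at a given expected-count scale
make_radial_profile <- function(centers, amps, sigmas,
                                q = seq(0.05, 0.60, length.out = 220),
                                bg_amp = 0, bg_decay = 6, noise_seed = NULL) {
  y <- bg_amp * exp(-q * bg_decay)
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(q - centers[i])^2 / (2 * sigmas[i]^2))
  if (!is.null(noise_seed)) {
    set.seed(noise_seed)
    y <- rpois(length(q), y)
  }
  profile1d("radial_q", q, y, rep(50L, length(q)))
}

# azimuthal profile with 180-degree paired circular Gaussian peaks
make_chi_profile <- function(chi0, width, amp1 = 50, amp2 = 40,
                             baseline = 5, n = 90, noise_seed = NULL) {
  chi <- (seq_len(n) - 0.5) * 360 / n
  g <- function(c0) {
    d <- (chi - c0 + 180) %% 360 - 180
    exp(-d^2 / (2 * width^2))
  }
  y <- baseline + amp1 * g(chi0) + amp2 * g(chi0 + 180)
  if (!is.null(noise_seed)) {
    set.seed(noise_seed)
    y <- rpois(length(chi), 20 * y) / 20
  }
  profile1d("azimuthal_chi", chi, y, rep(30L, n))
}

# circularly shift an azimuthal profile by a whole number of bins
shift_chi_profile <- function(profile, shift_deg) {
  n <- length(profile$grid)
  binw <- 360 / n
  k <- round(shift_deg / binw)
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  profile1d("azimuthal_chi", profile$grid, profile$intensity[idx],
            profile$counts_per_bin[idx])
}

# two integer-offset views of one larger speckle so the imposed shift is
# exact (no boundary fill)
speckle_views <- function(size, shift_rc, feature_scale = 8, seed = 5) {
  big <- speckle_pair(size + 2 * max(abs(shift_rc)) + 2L,
                      feature_scale = feature_scale, seed = seed)$reference
  m <- max(abs(shift_rc)) + 1L
  ref <- big[m + seq_len(size), m + seq_len(size)]
  def <- big[m + seq_len(size) - shift_rc[1], m + seq_len(size) - shift_rc[2]]
  list(reference = ref, deformed = def)
}
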