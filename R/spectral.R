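# Frequency-domain motif prior.
#
# Regulatory motifs are mostly 6-20 bp wide. In the discrete Fourier spectrum
# of a length-L per-base likelihood profile, motif-scale variation lands at
# indices roughly L/20..L/6, while long repeats concentrate below and
# noise-like structure above that band. The prior rewards in-band spectral
# mass: L_att = 1 - sum_i w_i a_i, with a the L1-normalized magnitude spectrum
# over positive frequencies (DC excluded) and w a plateau weight over the band
# with hyperbolic shoulders controlled by a smoothing factor s.

#' Configuration for the Fourier motif prior
#'
#' Cutoffs default to the motif band for a length-L profile: high cutoff
#' `C_H = L/6` and low cutoff `C_L = L/20`, kept real-valued (not rounded).
#'
#' @param s Smoothing factor for the shoulder decay (default 5).
#' @param lambda Weight of the prior in the combined loss (default 0.002).
#' @param eps Numerical floor added to the L1 normalizer (default 1e-8); a
#'   profile with zero non-DC spectrum therefore scores `L_att ~ 1`, maximally
#'   penalizing flat likelihood landscapes.
#' @param c_high,c_low Optional explicit cutoffs; `NULL` means `L/6` and
#'   `L/20` computed from the profile length at evaluation time.
#' @return A `fourier_prior_config` list.
#' @export
fourier_prior_config <- function(s = 5, lambda = 0.002, eps = 1e-8,
                                 c_high = NULL, c_low = NULL) {
  stopifnot(s > 0, lambda >= 0, eps > 0)
  structure(
    list(s = s, lambda = lambda, eps = eps, c_high = c_high, c_low = c_low),
    class = "fourier_prior_config"
  )
}

resolve_cutoffs <- function(L, config) {
  c_high <- config$c_high %||% (L / 6)
  c_low <- config$c_low %||% (L / 20)
  if (!(0 < c_low && c_low < c_high && c_high <= L / 2)) {
    rlang::abort("cutoffs must satisfy 0 < C_L < C_H <= L/2")
  }
  list(c_high = c_high, c_low = c_low)
}

#' Spectral weights over positive frequency indices
#'
#' Weight 1 on the motif band `C_L <= i <= C_H`; below the band
#' `w_i = 1/(1 + (C_L - i)/s)` and above it `w_i = 1/(1 + (i - C_H)/s)`.
#'
#' @param L Profile length (L >= 4).
#' @param config A [fourier_prior_config()].
#' @return Numeric vector of length `floor(L/2)`, entries in (0, 1].
#' @examples
#' w <- spectral_weights(350, fourier_prior_config())
#' w[175] # far above the band, strongly down-weighted
#' @export
spectral_weights <- function(L, config = fourier_prior_config()) {
  stopifnot(L >= 4)
  cuts <- resolve_cutoffs(L, config)
  i <- seq_len(L %/% 2)
  w <- rep(1, length(i))
  lo <- i < cuts$c_low
  hi <- i > cuts$c_high
  w[lo] <- 1 / (1 + (cuts$c_low - i[lo]) / config$s)
  w[hi] <- 1 / (1 + (i[hi] - cuts$c_high) / config$s)
  w
}

profile_spectrum <- function(profile, eps) {
  L <- length(profile)
  K <- L %/% 2
  m <- Mod(stats::fft(profile))[2:(K + 1)]
  a <- m / (sum(m) + eps)
  list(m = m, a = a)
}

#' Fourier prior loss of a likelihood profile
#'
#' Applies the discrete Fourier transform to the profile, takes magnitudes at
#' positive frequencies 1..floor(L/2) (DC excluded), L1-normalizes with floor
#' `eps`, and returns `L_att = 1 - sum(w * a)`.
#'
#' @param profile Finite numeric vector (length L >= 4), typically the
#'   per-position predicted probability of the observed base.
#' @param config A [fourier_prior_config()].
#' @return List with `l_att` (scalar in \[0, 1\]), `a` (normalized magnitude
#'   spectrum) and `w` (spectral weights).
#' @export
fourier_prior_loss <- function(profile, config = fourier_prior_config()) {
  if (!all(is.finite(profile))) {
    rlang::abort("profile contains non-finite values")
  }
  L <- length(profile)
  w <- spectral_weights(L, config)
  sp <- profile_spectrum(profile, config$eps)
  list(l_att = 1 - sum(w * sp$a), a = sp$a, w = w)
}

#' Analytic gradient of the Fourier prior loss
#'
#' Gradient of [fourier_prior_loss()]'s `l_att` with respect to the profile.
#'
#' @inheritParams fourier_prior_loss
#' @return Numeric vector, same length as `profile`.
#' @export
fourier_prior_grad <- function(profile, config = fourier_prior_config()) {
  L <- length(profile)
  K <- L %/% 2
  w <- spectral_weights(L, config)
  ft <- stats::fft(profile)[2:(K + 1)]
  re <- Re(ft)
  im <- Im(ft)
  m <- sqrt(re^2 + im^2)
  S <- sum(m) + config$eps
  a <- m / S
  dLdm <- -(w - sum(w * a)) / S
  # dm_i/dp_t = (Re_i cos(th) - Im_i sin(th)) / m_i with th = 2*pi*i*t/L
  safe_m <- ifelse(m > 0, m, 1)
  coef_re <- ifelse(m > 0, dLdm * re / safe_m, 0)
  coef_im <- ifelse(m > 0, dLdm * im / safe_m, 0)
  t0 <- 0:(L - 1)
  theta <- outer(seq_len(K), t0, function(i, t) 2 * pi * i * t / L)
  drop(coef_re %*% cos(theta) - coef_im %*% sin(theta))
}

#' In-band spectral fraction of a profile
#'
#' Fraction of the L1-normalized non-DC magnitude spectrum that falls inside
#' the motif band `C_L <= i <= C_H`. A diagnostic used to compare likelihood
#' landscapes of models trained with and without the prior.
#'
#' @inheritParams fourier_prior_loss
#' @return Scalar in \[0, 1\].
#' @export
inband_spectral_fraction <- function(profile, config = fourier_prior_config()) {
  L <- length(profile)
  cuts <- resolve_cutoffs(L, config)
  sp <- profile_spectrum(profile, config$eps)
  i <- seq_along(sp$a)
  sum(sp$a[i >= cuts$c_low & i <= cuts$c_high])
}
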