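#' Latent-source coupling models for synthetic EEG
#'
#' A coupling model describes how 14 scalp channels arise from independent
#' unit-variance band-limited latent sources by linear mixing, plus
#' per-channel broadband noise and low-frequency drift. Zero-lag channel
#' correlations then have the closed form
#' \deqn{\rho_{ij} = \frac{w_i \cdot w_j}{\sqrt{(w_i \cdot w_i + \sigma_i^2)(w_j \cdot w_j + \sigma_j^2)}}}
#' which [analytic_channel_correlation()] evaluates and which the test
#' suite uses as the generator's oracle.
#'
#' The three regime presets encode the coupling structure reported for the
#' two problem-solving behavioral patterns:
#'
#' * both task regimes: all pairwise correlations among the six frontal
#'   sensors (AF3, F7, F3, AF4, F4, F8) at or above 0.45, with the
#'   within-hemisphere pairs (F7,F3) and (F4,F8) at or above 0.85;
#' * `KATA`: weak temporoparietal-frontal coupling, corr(P7, F7/F3) and
#'   corr(P8, F4/F8) inside \[0.21, 0.34\];
#' * `CPDnA`: strong temporoparietal-frontal coupling, the same pairs
#'   inside \[0.68, 0.73\];
#' * `control`: identical frontal structure but zero
#'   temporoparietal-frontal coupling (used for null experiments).
#'
#' @name coupling_model
NULL

# Fixed structural parameters of the factor model. sigma2 is the broadband
# noise variance per channel (channel variances are normalized to 1, so
# sigma2 is also the noise fraction).
.coupling_base <- list(
  sigma2    = 0.05,
  a         = 0.75,   # AF3/AF4 loading on the global frontal source
  g         = 0.72,   # F7/F3/F4/F8 loading on the global frontal source
  r_pair    = 0.88,   # target corr(F7,F3) and corr(F4,F8)
  jitter    = 0.02,
  drift_amp = 2.0,
  band      = c(4, 30)
)

.regime_bounds <- list(
  KATA    = c(0.21, 0.34),
  CPDnA   = c(0.68, 0.73),
  control = c(0, 0)
)

new_coupling_model <- function(mixing_weights, noise_sd, regime_label,
                               targets, source_spectrum = .coupling_base$band,
                               drift_amplitude = .coupling_base$drift_amp) {
  channel_names <- aes_montage()
  stopifnot(nrow(mixing_weights) == length(channel_names),
            length(noise_sd) == length(channel_names))
  if (any(!is.finite(mixing_weights))) stop("mixing weights must be finite")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  rownames(mixing_weights) <- channel_names
  structure(
    list(channel_names = channel_names,
         mixing_weights = mixing_weights,
         source_spectrum = source_spectrum,
         noise_sd = noise_sd,
         drift_amplitude = drift_amplitude,
         regime_label = regime_label,
         targets = targets),
    class = "coupling_model"
  )
}

#' Build a coupling model for a behavioral regime
#'
#' Constructs the mixing weights realizing a regime's target correlations
#' through a structured factor model: one global frontal source, one pair
#' source per hemisphere (driving F7/F3 and F4/F8 and, scaled by the
#' regime's temporoparietal coupling, P7/P8), and a private source per
#' channel topping each variance up to 1 minus the noise fraction. The
#' construction is exact: [analytic_channel_correlation()] of the returned
#' model reproduces the targets to machine precision.
#'
#' Per-subject variability is modeled by jittering the target correlations
#' uniformly by +/-0.02 under `seed`, truncated to the regime interval.
#'
#' @param regime `"KATA"`, `"CPDnA"` or `"control"`.
#' @param seed Integer seed for the jitter draws.
#' @return A `coupling_model`.
#' @export
#' @examples
#' m <- make_regime_config("CPDnA", seed = 1)
#' analytic_channel_correlation(m)["P8", "F8"]
make_regime_config <- function(regime, seed = 1L) {
  if (!is.character(regime) || length(regime) != 1 ||
      !regime %in% names(.regime_bounds)) {
    stop("unknown regime '", paste(regime, collapse = ","),
         "'; valid regimes: KATA, CPDnA, control")
  }
  p <- .coupling_base
  bounds <- .regime_bounds[[regime]]
  mid <- mean(bounds)
  jit <- with_seed(seed, stats::runif(3, -p$jitter, p$jitter))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  r_pair <- clamp(p$r_pair + jit[1], p$r_pair - p$jitter, p$r_pair + p$jitter)
  if (regime == "control") {
    r_pf <- c(0, 0)
  } else {
    r_pf <- clamp(mid + jit[2:3], bounds[1], bounds[2])
  }

  ch <- aes_montage()
  n <- length(ch)
  l <- sqrt(r_pair - p$g^2)  # pair-source loading so corr(F7,F3) = r_pair
  # Structural columns: global frontal G, left pair L, right pair R.
  W <- matrix(0, n, 3, dimnames = list(ch, c("G", "L", "R")))
  W[c("AF3", "AF4"), "G"] <- p$a
  W[c("F7", "F3", "F4", "F8"), "G"] <- p$g
  W[c("F7", "F3"), "L"] <- l
  W[c("F4", "F8"), "R"] <- l
  # P7/P8 load on (G, pair) proportionally, giving corr(P7, F7) = r_pf
  # exactly: r_pf/r_pair * (g^2 + l^2) = r_pf.
  W["P7", c("G", "L")] <- r_pf[1] / r_pair * c(p$g, l)
  W["P8", c("G", "R")] <- r_pf[2] / r_pair * c(p$g, l)

  struct_var <- rowSums(W^2)
  priv_var <- 1 - p$sigma2 - struct_var
  if (any(priv_var < 0)) stop("infeasible targets: negative private variance")
  W <- cbind(W, diag(sqrt(priv_var)))
  colnames(W) <- c("G", "L", "R", paste0("priv_", ch))

  new_coupling_model(W, noise_sd = rep(sqrt(p$sigma2), n),
                     regime_label = regime,
                     targets = list(r_pair = r_pair,
                                    r_pf_left = r_pf[1], r_pf_right = r_pf[2]))
}

#' Closed-form channel correlations of a coupling model
#'
#' Evaluates the correlation matrix implied by the mixing weights and noise
#' scales under independent unit-variance sources. Serves as the analytic
#' oracle against which simulated recordings are checked.
#'
#' @param model A `coupling_model`.
#' @return A `correlation_matrix` over the 14-channel montage.
#' @export
analytic_channel_correlation <- function(model) {
  stopifnot(inherits(model, "coupling_model"))
  W <- model$mixing_weights
  V <- W %*% t(W) + diag(model$noise_sd^2)
  v <- diag(V)
  if (any(v <= .Machine$double.eps)) {
    stop("zero-variance channel: ",
         paste(model$channel_names[v <= .Machine$double.eps], collapse = ", "))
  }
  C <- V / sqrt(outer(v, v))
  new_correlation_matrix(C, model$channel_names)
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("Coupling model, regime '%s'\n", x$regime_label))
  cat(sprintf("  %d channels, %d latent sources, source band %g-%g Hz\n",
              nrow(x$mixing_weights), ncol(x$mixing_weights),
              x$source_spectrum[1], x$source_spectrum[2]))
  cat(sprintf("  targets: pair %.3f, TPJ-frontal %.3f / %.3f\n",
              x$targets$r_pair, x$targets$r_pf_left, x$targets$r_pf_right))
  invisible(x)
}
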