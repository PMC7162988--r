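#' Mixture specification for free-fluorophore contamination
#'
#' Describes a pixel-level mixture of an intramolecular 1:1-type FRET
#' construct (intrinsic FRET probability \code{E0}, intrinsic stoichiometry
#' \code{S0}) with free donors and/or free acceptors. \code{r_free_donor}
#' is the ratio of free donors to construct donors; \code{r_free_acceptor}
#' the ratio of free acceptors to construct copies (counted by their
#' donors).
#'
#' @param E0 intrinsic FRET probability of the construct, in \code{[0, 1]}.
#' @param S0 intrinsic stoichiometry, strictly inside \code{(0, 1)}.
#' @param r_free_donor,r_free_acceptor contamination ratios, \code{>= 0}.
#' @return An object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(E0, S0 = 0.5, r_free_donor = 0,
                         r_free_acceptor = 0) {
  stopifnot(E0 >= 0, E0 <= 1, S0 > 0, S0 < 1,
            r_free_donor >= 0, r_free_acceptor >= 0)
  structure(list(E0 = E0, S0 = S0, r_free_donor = r_free_donor,
                 r_free_acceptor = r_free_acceptor),
            class = "mixture_spec")
}

#' Apparent E and S under free-donor contamination
#'
#' Free donors cannot transfer energy, so they dilute the FRET signal and
#' raise the apparent donor fraction. For a construct of intrinsic
#' \code{(E0, S0)} mixed with free donors at ratio
#' \code{r = n_D_free / n_D_construct}:
#' \deqn{E_{app} = \frac{1}{1 + (1 - E_0 + r)/E_0}, \qquad
#'       S_{app} = \frac{1 + r}{1/S_0 + r}.}
#' As \code{r} grows, the point moves along a trajectory towards the
#' pure-donor corner \code{(E = 0, S = 1)}.
#'
#' @param spec a [mixture_spec()] (with \code{E0 > 0}), or \code{E0}
#'   directly.
#' @param S0,r optional scalar overrides when \code{spec} is numeric.
#' @return A list with \code{E_app}, \code{S_app} (vectorized over
#'   \code{r}).
#' @export
apparent_es_free_donor <- function(spec, S0 = 0.5, r = 0) {
  if (inherits(spec, "mixture_spec")) {
    E0 <- spec$E0; S0 <- spec$S0; r <- spec$r_free_donor
  } else E0 <- spec
  stopifnot(E0 > 0, E0 <= 1, all(r >= 0))
  list(E_app = 1 / (1 + (1 - E0 + r) / E0),
       S_app = (1 + r) / (1 / S0 + r))
}

#' Apparent E and S under free-acceptor contamination
#'
#' Free acceptors are invisible to the donor-excitation channels once
#' crosstalk is corrected, so the apparent FRET probability is unchanged
#' while the stoichiometry drops. From the definition
#' \code{S = n_D / (n_D + n_A)} with the acceptor count increased by
#' \code{r} free acceptors per construct copy:
#' \deqn{E_{app} = E_0, \qquad S_{app} = \frac{1}{1/S_0 + r}.}
#' As \code{r} grows the point moves horizontally towards \code{S = 0}.
#'
#' @inheritParams apparent_es_free_donor
#' @return A list with \code{E_app}, \code{S_app}.
#' @export
apparent_es_free_acceptor <- function(spec, S0 = 0.5, r = 0) {
  if (inherits(spec, "mixture_spec")) {
    E0 <- spec$E0; S0 <- spec$S0; r <- spec$r_free_acceptor
  } else E0 <- spec
  stopifnot(all(r >= 0))
  list(E_app = rep(E0, length(r)),
       S_app = 1 / (1 / S0 + r))
}

#' Free-donor mixing trajectory in the E-S plane
#'
#' Eliminating the contamination ratio between the two apparent quantities
#' of the free-donor mixture gives a closed-form trajectory
#' \deqn{S_{app} = \frac{E_0 / E_{app}}{1/S_0 + E_0/E_{app} - 1},}
#' valid for \code{0 < E_app <= E0}. A tilted cloud in an experimental E-S
#' histogram that follows this curve indicates free-donor contamination,
#' and fitting it recovers the intrinsic \code{E0}.
#'
#' @param E0 intrinsic FRET probability.
#' @param S0 intrinsic stoichiometry.
#' @param E_app apparent FRET probabilities (vector), in \code{(0, E0]}.
#' @return The apparent stoichiometries \code{S_app}.
#' @export
mixing_trajectory <- function(E0, S0, E_app) {
  stopifnot(E0 > 0, S0 > 0, S0 < 1)
  if (any(E_app <= 0))
    stop("E_app must be strictly positive")
  q <- E0 / E_app
  q / (1 / S0 + q - 1)
}

#' Fit the intrinsic FRET probability from a tilted E-S cloud
#'
#' Least-squares fit of the free-donor mixing trajectory to observed
#' \code{(E_app, S_app)} pairs (e.g. per-cell medians), minimizing vertical
#' residuals in S over the intrinsic \code{E0}.
#'
#' @param E_app,S_app observed pairs (\code{>= 10} recommended), spanning a
#'   segment of the trajectory.
#' @param S0 known intrinsic stoichiometry.
#' @return A list with \code{E0_hat}, \code{rmse} (root-mean-square S
#'   residual), \code{n}, and \code{poor_fit} (TRUE when the residual
#'   spread rivals the S spread of the data — e.g. a horizontal
#'   free-acceptor series, which this model cannot describe).
#' @export
fit_intrinsic_e0 <- function(E_app, S_app, S0 = 0.5) {
  ok <- is.finite(E_app) & is.finite(S_app) & E_app > 0
  E_app <- E_app[ok]; S_app <- S_app[ok]
  if (length(E_app) < 2) stop("at least 2 valid (E_app, S_app) pairs needed")
  if (diff(range(E_app)) < 1e-8)
    stop("degenerate input: all points share one E_app")
  obj <- function(E0) mean((S_app - mixing_trajectory(E0, S0, E_app))^2)
  opt <- optimize(obj, c(max(E_app) * (1 - 1e-9), 1), tol = 1e-10)
  # E0 must be >= max(E_app) for the trajectory to cover the data; also
  # search below in case of noise pushing E_app above E0
  opt2 <- optimize(obj, c(1e-6, 1), tol = 1e-10)
  best <- if (opt2$objective < opt$objective) opt2 else opt
  rmse <- sqrt(best$objective)
  list(E0_hat = best$minimum, rmse = rmse, n = length(E_app),
       poor_fit = rmse > 0.5 * sd(S_app))
}
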