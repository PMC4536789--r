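# Closed-form polymer models of 3C/Hi-C contact-frequency decay.
#
# The core model combines the freely-jointed-chain and Kratky-Porod
# worm-like-chain descriptions of the chromatin fiber: the cross-linking
# frequency X(s) between two sites separated by s kb along the genome is
#
#   X(s) = K * 0.53 * beta^(-3/2) * exp(-2 / beta^2) * (L * S)^(-3)
#
# where beta is a dimensionless reduced separation, K an arbitrary-scale
# cross-linking efficiency, L the linear mass density (nm of fiber per kb
# of DNA) and S the Kuhn statistical segment (kb, chromatin flexibility).
# For an unconstrained fiber beta = s/S; under the statistical-helix
# description of constrained supranucleosomal dynamics beta acquires a
# periodic modulation controlled by the mean helix diameter D (nm) and
# mean pitch P (nm).

# Constants of the combined FJC/WLC contact-frequency law; fixed, not fitted.
.KP_PREFACTOR <- 0.53
.KP_POWER <- -3 / 2
.KP_EXP_COEF <- -2

# Below this reduced separation exp(-2/beta^2) underflows; the analytic
# limit of X as beta -> 0+ is 0, so the curve is returned as exactly 0.
.BETA_UNDERFLOW <- 1e-3

#' Reduced separation of an unconstrained chromatin fiber
#'
#' For a chromatin fiber free of supranucleosomal constraints the reduced
#' (dimensionless) separation between two sites is simply the genomic
#' separation measured in Kuhn segments, `s / S`.
#'
#' @param s Genomic separation in kb; strictly positive (vectorized).
#' @param S Kuhn statistical segment in kb; strictly positive scalar.
#' @return Numeric vector of reduced separations.
#' @seealso [beta_helix()] for the constrained (statistical helix) form,
#'   [contact_frequency()] for the resulting contact frequency.
#' @examples
#' beta_unconstrained(c(2.7, 5.4), S = 2.7)
#' @export
beta_unconstrained <- function(s, S) {
  stopifnot(is.numeric(s), is.numeric(S), length(S) == 1L)
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("`s` must be finite and strictly positive")
  }
  if (!is.finite(S) || S <= 0) stop("`S` must be finite and strictly positive")
  s / S
}

#' Reduced separation under the statistical-helix model
#'
#' Constraints acting on supranucleosomal chromatin dynamics are described
#' as if the fiber were, on average, folded into a helix of mean diameter
#' `D` (nm) and mean pitch `P` (nm). The spatial distance between two sites
#' then oscillates with genomic separation, and the reduced separation is
#'
#' \deqn{\beta = \frac{\sqrt{D^2 \sin^2\!\big[\pi L s / \sqrt{\pi^2 D^2 + P^2}\big]
#'   + P^2 L^2 s^2 / (\pi^2 D^2 + P^2)}}{L\,S}}
#'
#' With `D = 0` (degenerate, straight-chain helix) this reduces exactly to
#' [beta_unconstrained()]. The genomic period of the modulation equals the
#' helix-turn length returned by [helix_turn_length()].
#'
#' @inheritParams beta_unconstrained
#' @param L Linear mass density in nm/kb; strictly positive scalar.
#' @param D Mean helix diameter in nm; non-negative scalar.
#' @param P Mean helix pitch in nm; strictly positive scalar.
#' @return Numeric vector of reduced separations.
#' @examples
#' beta_helix(50, L = 9.7, S = 2.7, D = 255, P = 201)
#' @export
beta_helix <- function(s, L, S, D, P) {
  stopifnot(
    is.numeric(s), is.numeric(L), is.numeric(S), is.numeric(D), is.numeric(P),
    length(L) == 1L, length(S) == 1L, length(D) == 1L, length(P) == 1L
  )
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("`s` must be finite and strictly positive")
  }
  if (L <= 0) stop("`L` must be strictly positive")
  if (S <= 0) stop("`S` must be strictly positive")
  if (D < 0) stop("`D` must be non-negative")
  if (P <= 0) stop("`P` must be strictly positive")
  denom2 <- pi^2 * D^2 + P^2
  sqrt(D^2 * sin(pi * L * s / sqrt(denom2))^2 + P^2 * L^2 * s^2 / denom2) /
    (L * S)
}

#' Contact frequency from a reduced separation
#'
#' Evaluates the combined freely-jointed-chain / worm-like-chain law
#' \deqn{X = K \cdot 0.53 \cdot \beta^{-3/2} e^{-2/\beta^2} (L S)^{-3}}
#' relating the cross-linking (contact) frequency to the reduced separation
#' `beta`. The value is on an arbitrary relative scale absorbed by `K`
#' (nominally mol l^-1 nm^3). As `beta` tends to 0 the frequency tends to 0;
#' reduced separations below `1e-3` return exactly 0 so that the exponential
#' underflow never produces `NaN` from the `0 * Inf` product.
#'
#' @param beta Reduced separation(s), non-negative (vectorized).
#' @param K Cross-linking efficiency scale, `>= 0`; recycled along `beta`.
#' @param L Linear mass density, nm/kb, `> 0`; recycled along `beta`.
#' @param S Kuhn segment, kb, `> 0`; recycled along `beta`.
#' @return Numeric vector of relative contact frequencies.
#' @examples
#' contact_frequency(sqrt(2), K = 1, L = 1, S = 1) # 0.53 * 2^(-3/4) / e
#' @export
contact_frequency <- function(beta, K, L, S) {
  stopifnot(is.numeric(beta), is.numeric(K), is.numeric(L), is.numeric(S))
  if (any(!is.finite(beta)) || any(beta < 0)) {
    stop("`beta` must be finite and non-negative")
  }
  if (any(K < 0)) stop("`K` must be non-negative")
  if (any(L <= 0) || any(S <= 0)) stop("`L` and `S` must be strictly positive")
  n <- length(beta)
  K <- rep_len(K, n); L <- rep_len(L, n); S <- rep_len(S, n)
  x <- numeric(n)
  ok <- beta >= .BETA_UNDERFLOW
  b <- beta[ok]
  x[ok] <- K[ok] * .KP_PREFACTOR * b^.KP_POWER * exp(.KP_EXP_COEF / b^2) *
    (L[ok] * S[ok])^(-3)
  x
}

#' Model contact-frequency curve over genomic separations
#'
#' Composes the reduced-separation maps with [contact_frequency()]: the
#' unconstrained-chain curve when `D` and `P` are absent, the
#' statistical-helix curve otherwise.
#'
#' @param s Genomic separations in kb, strictly positive.
#' @param K,L,S Local chromatin parameters (see [contact_frequency()]).
#' @param D,P Optional statistical-helix parameters (nm); supply both or
#'   neither.
#' @return Numeric vector of relative contact frequencies, one per `s`.
#' @examples
#' model_curve(seq(5, 250, by = 5), K = 1.07e3, L = 9.7, S = 2.7,
#'             D = 255, P = 201)
#' @export
model_curve <- function(s, K, L, S, D = NULL, P = NULL) {
  if (is.null(D) != is.null(P)) {
    stop("supply both `D` and `P` for a helix curve, or neither")
  }
  beta <- if (is.null(D)) {
    beta_unconstrained(s, S)
  } else {
    beta_helix(s, L = L, S = S, D = D, P = P)
  }
  contact_frequency(beta, K = K, L = L, S = S)
}

#' Genomic length of one statistical-helix turn
#'
#' The genomic DNA content `Sh` (kb) of one turn of the statistical helix,
#' \deqn{S_h = \sqrt{(\pi D)^2 + P^2} / L.}
#' This is also the genomic period of the contact-frequency modulation of
#' the helix model. The value is returned at full precision; round only
#' for display.
#'
#' @param D Mean helix diameter, nm, `>= 0`.
#' @param P Mean helix pitch, nm, `> 0`.
#' @param L Linear mass density, nm/kb, `> 0`.
#' @return Helix-turn length in kb.
#' @examples
#' helix_turn_length(D = 287, P = 160, L = 9.45) # ~96.9 kb (liver gene-rich)
#' helix_turn_length(D = 255, P = 201, L = 9.70) # ~85.2 kb (mESC gene-rich)
#' @export
helix_turn_length <- function(D, P, L) {
  stopifnot(is.numeric(D), is.numeric(P), is.numeric(L))
  if (any(L <= 0)) stop("`L` must be strictly positive")
  if (any(D < 0)) stop("`D` must be non-negative")
  if (any(P <= 0)) stop("`P` must be strictly positive")
  sqrt((pi * D)^2 + P^2) / L
}

#' Globule power-law contact frequency
#'
#' Power-law scaling `X(s) = k * s^alpha` used to test globule ensembles
#' against observed decay curves: the equilibrium globule predicts
#' `alpha = -3/2`, the crumpled (fractal) globule `alpha = -1`; `alpha` may
#' also be fitted freely (see [fit_powerlaw()]).
#'
#' @param s Genomic separation in kb, strictly positive (vectorized).
#' @param k Prefactor, `> 0`.
#' @param alpha Scaling exponent (dimensionless, usually negative).
#' @return Numeric vector of relative contact frequencies.
#' @examples
#' powerlaw_frequency(10, k = 1, alpha = -1)
#' @export
powerlaw_frequency <- function(s, k, alpha) {
  stopifnot(is.numeric(s), is.numeric(k), is.numeric(alpha),
            length(k) == 1L, length(alpha) == 1L)
  if (any(s <= 0)) stop("`s` must be strictly positive")
  if (k <= 0) stop("`k` must be strictly positive")
  k * s^alpha
}

#' Linear mass density from nucleosome repeat length
#'
#' Converts a nucleosome repeat length (bp of DNA per nucleosome) into a
#' fiber linear mass density L (nm/kb) using a packing ratio of 6
#' nucleosomes per 11 nm of chromatin (the default `nm_per_nucleosome =
#' 11/6` nm), the value measured for chromatin in solution at physiological
#' salt. E.g. NRL 194 (mouse liver) gives L = 9.45 nm/kb and NRL 189
#' (mESC) gives L = 9.70 nm/kb.
#'
#' @param nrl_bp Nucleosome repeat length, bp per nucleosome, `> 0`.
#' @param nm_per_nucleosome Fiber nm contributed per nucleosome; default
#'   `11/6`.
#' @return Linear mass density in nm/kb.
#' @examples
#' linear_density_from_nrl(194)
#' linear_density_from_nrl(189)
#' @export
linear_density_from_nrl <- function(nrl_bp, nm_per_nucleosome = 11 / 6) {
  stopifnot(is.numeric(nrl_bp), is.numeric(nm_per_nucleosome))
  if (any(nrl_bp <= 0)) stop("`nrl_bp` must be strictly positive")
  if (any(nm_per_nucleosome <= 0)) {
    stop("`nm_per_nucleosome` must be strictly positive")
  }
  (1000 / nrl_bp) * nm_per_nucleosome
}
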