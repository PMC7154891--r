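## Tamura-92-type substitution model: two parameters, theta (equilibrium GC)
## and kappa (transition/transversion rate ratio). State order A, C, G, T.

NUC <- c("A", "C", "G", "T")
.GC_STATES <- c(2L, 3L)   # C, G
.AT_STATES <- c(1L, 4L)   # A, T
.TS_PAIR <- matrix(FALSE, 4, 4)  # transitions: A<->G, C<->T
.TS_PAIR[1, 3] <- .TS_PAIR[3, 1] <- .TS_PAIR[2, 4] <- .TS_PAIR[4, 2] <- TRUE

#' Equilibrium base frequencies of the T92 model
#'
#' @param theta Equilibrium GC content, in (0, 1).
#' @return Numeric vector of length 4 (A, C, G, T) with
#'   \eqn{\pi_G = \pi_C = \theta/2} and \eqn{\pi_A = \pi_T = (1-\theta)/2}.
#' @export
t92_frequencies <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, theta < 1)
  c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
}

#' T92 rate matrix
#'
#' Builds the 4x4 generator with off-diagonal rate \eqn{\kappa \pi_j} for
#' transitions and \eqn{\pi_j} for transversions, scaled so that the expected
#' substitution rate at the matrix's own equilibrium is one per unit branch
#' length. Rows sum to zero.
#'
#' @param theta Equilibrium GC content, in (0, 1).
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return 4x4 matrix with dimnames A, C, G, T.
#' @examples
#' Q <- t92_rate_matrix(0.3, 2)
#' t92_frequencies(0.3) %*% Q   # stationarity: zero vector
#' @export
t92_rate_matrix <- function(theta, kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  pi <- t92_frequencies(theta)
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(NUC, NUC))
  Q[.TS_PAIR] <- Q[.TS_PAIR] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # expected rate at equilibrium
  Q / mu
}

#' Equilibrium GC content implied by AT->GC and GC->AT substitution rates
#'
#' The equilibrium GC frequency (GC*) is the rate at which an A or T site
#' gains G/C divided by the total turnover rate between the two classes:
#' \eqn{GC^* = r_{AT \to GC} / (r_{AT \to GC} + r_{GC \to AT})}. For a T92
#' generator these per-state rates are \eqn{\theta(1+\kappa)/2} and
#' \eqn{(1-\theta)(1+\kappa)/2}, so GC* equals theta exactly.
#'
#' @param rate_at_to_gc Substitution rate from an A or T base to G or C.
#' @param rate_gc_to_at Substitution rate from a G or C base to A or T.
#' @return GC* in [0, 1].
#' @export
gc_star <- function(rate_at_to_gc, rate_gc_to_at) {
  stopifnot(rate_at_to_gc >= 0, rate_gc_to_at >= 0)
  tot <- rate_at_to_gc + rate_gc_to_at
  if (tot <= 0)
    stop("GC* undefined: both class-switching rates are zero")
  rate_at_to_gc / tot
}

#' GC* of an arbitrary 4x4 nucleotide generator
#'
#' Extracts the per-state class-switching rates (mean rate from an A/T state
#' into \{G,C\}, and from a G/C state into \{A,T\}) and applies
#' \code{\link{gc_star}}.
#'
#' @param Q 4x4 generator in A, C, G, T order.
#' @return GC* in [0, 1].
#' @export
gc_star_from_rates <- function(Q) {
  stopifnot(is.matrix(Q), all(dim(Q) == 4L))
  r_at_gc <- mean(rowSums(Q[.AT_STATES, .GC_STATES, drop = FALSE]))
  r_gc_at <- mean(rowSums(Q[.GC_STATES, .AT_STATES, drop = FALSE]))
  gc_star(r_at_gc, r_gc_at)
}

## Spectral decomposition of Q(theta, kappa), cached per parameter pair.
## T92 is reversible, so D^{1/2} Q D^{-1/2} is symmetric and the
## decomposition is numerically stable.
t92_eigen <- function(theta, kappa) {
  Q <- t92_rate_matrix(theta, kappa)
  pi <- t92_frequencies(theta)
  s <- sqrt(pi)
  B <- Q * outer(s, 1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / s,          # D^{-1/2} V
       left = t(e$vectors * s))        # V' D^{1/2}
}

#' T92 transition probability matrix
#'
#' @param theta Equilibrium GC content, in (0, 1).
#' @param kappa Transition/transversion ratio, > 0.
#' @param t Branch length (expected substitutions/site at equilibrium), >= 0.
#' @return Row-stochastic 4x4 matrix P(t) = exp(Qt).
#' @export
t92_transition_prob <- function(theta, kappa, t) {
  stopifnot(is.numeric(t), length(t) == 1L)
  if (t < 0) stop("branch length must be non-negative")
  ed <- t92_eigen(theta, kappa)
  P <- ed$right %*% (exp(ed$values * t) * ed$left)
  dimnames(P) <- list(NUC, NUC)
  ## clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

## Fast path used by the likelihood engine: P(t) for many branch lengths
## from one decomposition.
t92_pmats <- function(eig, tvec) {
  lapply(tvec, function(t) {
    P <- eig$right %*% (exp(eig$values * t) * eig$left)
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

#' Discrete-gamma rate categories
#'
#' Equal-probability categories of a mean-one gamma distribution
#' (shape = rate = alpha); the category rate is the conditional mean of the
#' gamma density over the category's quantile band, renormalised so the
#' weighted mean is exactly one.
#'
#' @param alpha Gamma shape parameter, > 0.
#' @param k Number of categories (default 4).
#' @return List with \code{rates} (length k) and \code{weights}
#'   (all \code{1/k}).
#' @examples
#' discrete_gamma_rates(0.5)$rates
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0) stop("gamma shape alpha must be positive")
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k == 1L) return(list(rates = 1, weights = 1))
  breaks <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  ## E[X 1{a < X < b}] for X ~ Gamma(alpha, alpha) is
  ## F_{alpha+1}(b) - F_{alpha+1}(a) with the same rate.
  cdf1 <- c(0, stats::pgamma(breaks, shape = alpha + 1, rate = alpha), 1)
  rates <- diff(cdf1) * k
  rates <- rates / mean(rates)
  list(rates = rates, weights = rep(1 / k, k))
}
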