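#' Nucleotide substitution model
#'
#' Builds a time-reversible rate matrix for JC69, HKY85 or GTR, optionally
#' with a proportion of invariant sites and gamma-distributed rate
#' variation across sites. The generator Q is assembled GTR-style from
#' exchangeabilities and stationary base frequencies and normalised so that
#' the mean substitution rate at stationarity is 1, i.e. branch lengths are
#' expected substitutions per site. Flag semantics mirror the Seq-Gen
#' conventions: `tstv` is the transition/transversion *ratio* (converted
#' internally to the HKY kappa), `rates` lists the six exchangeabilities in
#' the order AC, AG, AT, CG, CT, GT, and `freqs` is (A, C, G, T).
#'
#' @param model `"JC69"`, `"HKY85"` or `"GTR"`.
#' @param freqs stationary base frequencies (A, C, G, T); must sum to 1.
#'   JC69 forces 0.25 each.
#' @param tstv transition/transversion ratio (HKY85 only; default 0.5
#'   with equal frequencies, i.e. no transition bias).
#' @param rates six GTR exchangeabilities, order AC, AG, AT, CG, CT, GT
#'   (GTR only).
#' @param p_invariant proportion of invariant sites in `[0, 1)`.
#' @param gamma_shape shape of the mean-1 gamma distribution of site rates,
#'   or `NULL` for no rate variation.
#' @param gamma_categories number of equal-probability discrete gamma
#'   categories; 0 means a continuous gamma.
#' @return object of class `substitution_model` carrying the normalised
#'   generator `Q`, its spectral decomposition, and the rate-variation
#'   settings.
#' @examples
#' substitution_model("HKY85", freqs = c(0.3, 0.2, 0.2, 0.3), tstv = 3.0)
#' @export
substitution_model <- function(model = c("JC69", "HKY85", "GTR"),
                               freqs = c(0.25, 0.25, 0.25, 0.25),
                               tstv = NULL, rates = NULL,
                               p_invariant = 0, gamma_shape = NULL,
                               gamma_categories = 0L) {
  model <- match.arg(model)
  if (model == "JC69") freqs <- rep(0.25, 4)
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 4 positive values (A, C, G, T) summing to 1")
  freqs <- freqs / sum(freqs)
  if (p_invariant < 0 || p_invariant >= 1)
    stop("p_invariant must be in [0, 1)")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")

  ex <- switch(model,
    JC69 = rep(1, 6),
    HKY85 = {
      if (is.null(tstv)) tstv <- 0.5
      # convert ts/tv ratio R to kappa: R = kappa * (pA pG + pC pT) / tv_sum
      ts_sum <- freqs[1] * freqs[3] + freqs[2] * freqs[4]
      tv_sum <- freqs[1] * freqs[2] + freqs[1] * freqs[4] +
                freqs[2] * freqs[3] + freqs[3] * freqs[4]
      kappa <- tstv * tv_sum / ts_sum
      c(1, kappa, 1, 1, kappa, 1)  # AC, AG, AT, CG, CT, GT
    },
    GTR = {
      if (is.null(rates) || length(rates) != 6L || any(rates < 0))
        stop("GTR needs 6 non-negative exchangeabilities (AC, AG, AT, CG, CT, GT)")
      rates
    })

  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- ex[k] * freqs[j]
    Q[j, i] <- ex[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))     # mean rate at stationarity
  Q <- Q / mu

  # spectral decomposition of the reversible generator via its symmetrised
  # form S = D^{1/2} Q D^{-1/2}; P(t) = L diag(exp(lambda t)) R^T with
  # L = D^{-1/2} U, R = D^{1/2} U.
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  L <- diag(1 / d) %*% eig$vectors
  R <- diag(d) %*% eig$vectors

  structure(list(model = model, freqs = stats::setNames(freqs, NUC),
                 exchangeabilities = ex, Q = Q,
                 lambda = eig$values, L = L, R = R,
                 p_invariant = p_invariant, gamma_shape = gamma_shape,
                 gamma_categories = as.integer(gamma_categories)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model:", x$model, "\n")
  cat("  base frequencies:", paste(sprintf("%s=%.3g", NUC, x$freqs),
                                   collapse = " "), "\n")
  if (x$model == "GTR")
    cat("  exchangeabilities (AC AG AT CG CT GT):",
        paste(signif(x$exchangeabilities, 4), collapse = " "), "\n")
  if (x$p_invariant > 0)
    cat("  proportion invariant:", x$p_invariant, "\n")
  if (!is.null(x$gamma_shape))
    cat("  gamma rate variation: shape =", x$gamma_shape,
        if (x$gamma_categories > 0)
          paste0("(", x$gamma_categories, " discrete categories)")
        else "(continuous)", "\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for the model's normalised generator, computed from
#' the spectral decomposition of the reversible Q.
#'
#' @param model a [substitution_model()].
#' @param t branch length (expected substitutions per site).
#' @return 4 x 4 stochastic matrix, rows = ancestral state (A, C, G, T).
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  P <- model$L %*% (exp(model$lambda * t) * t(model$R))
  dimnames(P) <- list(NUC, NUC)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Discrete-gamma category rates: k equal-probability categories, each
## represented by its conditional mean (mean-1 overall).
.discrete_gamma_rates <- function(shape, k) {
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  k * diff(stats::pgamma(b, shape = shape + 1, rate = shape))
}

#' Draw per-site rate multipliers
#'
#' A site's rate is 0 with probability `p_invariant`; otherwise it is drawn
#' from a mean-1 gamma (continuous, or the conditional-mean rate of one of
#' `gamma_categories` equal-probability categories), or 1 when the model
#' has no gamma component. One multiplier per site, shared across all
#' branches of that site's gene tree.
#'
#' @param model a [substitution_model()].
#' @param n number of sites.
#' @return numeric vector of length `n`.
#' @export
site_rates <- function(model, n) {
  r <- if (is.null(model$gamma_shape)) {
    rep.int(1, n)
  } else if (model$gamma_categories > 0L) {
    cat_rates <- .discrete_gamma_rates(model$gamma_shape, model$gamma_categories)
    cat_rates[sample.int(model$gamma_categories, n, replace = TRUE)]
  } else {
    stats::rgamma(n, shape = model$gamma_shape, rate = model$gamma_shape)
  }
  if (model$p_invariant > 0)
    r[stats::runif(n) < model$p_invariant] <- 0
  r
}
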