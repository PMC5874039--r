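# Presence-background maximum-entropy suitability model.
#
# The model is a Gibbs density over the background cells with linear and
# quadratic features of each climate variable.  With feature matrix F and
# weights w, the penalized negative log-likelihood is
#
#   L(w) = -mean_presence(F w) + log( mean_background exp(F w) )
#          + sum_j lambda_j |w_j|
#
# which is convex; it is minimized by proximal gradient descent (soft
# thresholding) with backtracking line search.  Features are z-scored
# against the background so the L1 penalty treats variables comparably;
# lambda_j scales with the presence-sample standard deviation of feature j
# over sqrt(n_presences), multiplied by the regularization multiplier.
# Suitability is reported through the logistic transform
# p = plogis(eta - log Z_bg + H), where H is the entropy of the fitted
# Gibbs distribution over the background, so that a featureless model
# predicts 0.5 everywhere.

# linear + quadratic feature expansion with stored standardization
quadFeatures <- function(env, scaling = NULL, vars = NULL) {
  env <- as.data.frame(env)
  if (is.null(vars)) vars <- names(env)
  X <- as.matrix(env[, vars, drop = FALSE])
  if (is.null(scaling)) {
    mu <- colMeans(X)
    sd1 <- apply(X, 2, stats::sd)
    sd1[sd1 == 0] <- 1
    Z <- sweep(sweep(X, 2, mu, "-"), 2, sd1, "/")
    Q <- Z^2
    mu2 <- colMeans(Q)
    sd2 <- apply(Q, 2, stats::sd)
    sd2[sd2 == 0] <- 1
    scaling <- list(vars = vars, mu = mu, sd = sd1, mu2 = mu2, sd2 = sd2)
  } else {
    Z <- sweep(sweep(X, 2, scaling$mu, "-"), 2, scaling$sd, "/")
    Q <- Z^2
  }
  Qs <- sweep(sweep(Q, 2, scaling$mu2, "-"), 2, scaling$sd2, "/")
  F_ <- cbind(Z, Qs)
  colnames(F_) <- c(vars, paste0(vars, "^2"))
  list(F = F_, scaling = scaling)
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Default maximum-entropy run settings
#'
#' The conventional settings for this model family: an iteration cap of
#' 1000, a regularization multiplier of 1, and a convergence threshold of
#' 1e-5 on the change in penalized objective.
#'
#' @param maxIterations iteration cap for the solver.
#' @param regularizationMultiplier scales the per-feature L1 penalty.
#' @param convergenceTol stop when the objective improves by less than this.
#' @return a named list of settings.
#' @export
maxentSettings <- function(maxIterations = 1000L,
                           regularizationMultiplier = 1,
                           convergenceTol = 1e-5) {
  list(maxIterations = as.integer(maxIterations),
       regularizationMultiplier = regularizationMultiplier,
       convergenceTol = convergenceTol)
}

#' Fit a presence-background maximum-entropy suitability model
#'
#' @param presenceEnv data.frame of environmental values at presence points.
#' @param backgroundEnv data.frame of environmental values at background
#'   points.
#' @param settings see \code{\link{maxentSettings}}.
#' @return a fitted \linkS4class{NicheModel} (algorithm "maxent").  If the
#'   solver does not converge within the iteration cap the model is still
#'   returned, with \code{fit$converged = FALSE} and a warning.
#' @export
fitMaxent <- function(presenceEnv, backgroundEnv,
                      settings = maxentSettings()) {
  presenceEnv <- as.data.frame(presenceEnv)
  backgroundEnv <- as.data.frame(backgroundEnv)
  if (nrow(presenceEnv) < 5L)
    stop("at least 5 presence points are required")
  if (nrow(backgroundEnv) < 1L)
    stop("background must be non-empty")
  vars <- names(presenceEnv)
  fb <- quadFeatures(backgroundEnv, vars = vars)
  Fb <- fb$F
  Fp <- quadFeatures(presenceEnv, scaling = fb$scaling)$F
  m <- nrow(Fp)
  lambda <- settings$regularizationMultiplier *
    pmax(apply(Fp, 2, stats::sd), 0.05) / sqrt(m)
  fpbar <- colMeans(Fp)
  nb <- nrow(Fb)

  smooth <- function(w) {
    eta <- drop(Fb %*% w)
    -sum(fpbar * w) + logSumExp(eta) - log(nb)
  }
  gradSmooth <- function(w) {
    eta <- drop(Fb %*% w)
    p <- exp(eta - logSumExp(eta))
    -fpbar + drop(crossprod(Fb, p))
  }
  objective <- function(w) smooth(w) + sum(lambda * abs(w))

  w <- numeric(ncol(Fb))
  t_ <- 1
  fOld <- objective(w)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(settings$maxIterations)) {
    iters <- it
    g <- gradSmooth(w)
    gw <- smooth(w)
    repeat {   # backtracking on the smooth part
      wNew <- sign(w - t_ * g) * pmax(abs(w - t_ * g) - t_ * lambda, 0)
      d <- wNew - w
      if (smooth(wNew) <= gw + sum(g * d) + sum(d^2) / (2 * t_) ||
          t_ < 1e-10) break
      t_ <- t_ / 2
    }
    w <- wNew
    fNew <- objective(w)
    if (abs(fOld - fNew) < settings$convergenceTol) {
      converged <- TRUE
      break
    }
    fOld <- fNew
    t_ <- min(t_ * 2, 1e3)   # allow the step to grow again
  }
  if (!converged)
    warning(sprintf(
      "maxent solver did not converge within %d iterations (last change %.2e)",
      settings$maxIterations, abs(fOld - fNew)))

  etaB <- drop(Fb %*% w)
  logZ <- logSumExp(etaB)
  pB <- exp(etaB - logZ)
  H <- -sum(pB * log(pmax(pB, 1e-300)))
  trainEnv <- rbind(presenceEnv[vars], backgroundEnv[vars])
  refRanges <- rbind(min = apply(trainEnv, 2, min),
                     max = apply(trainEnv, 2, max))
  new("NicheModel", algorithm = "maxent", variables = vars,
      fit = list(weights = w, scaling = fb$scaling, lambda = lambda,
                 logZ = logZ, entropy = H, converged = converged,
                 iterations = iters, refRanges = refRanges,
                 trainEnv = trainEnv),
      trainingSummary = list(nPresence = m, nContrast = nb,
                             contrastMode = "background",
                             settings = settings))
}

predictMaxent <- function(model, env) {
  F_ <- quadFeatures(env, scaling = model@fit$scaling,
                     vars = model@variables)$F
  eta <- drop(F_ %*% model@fit$weights)
  stats::plogis(eta - model@fit$logZ + model@fit$entropy)
}
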