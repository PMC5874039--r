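# Logistic-regression and random-forest suitability models, plus the shared
# prediction surface.

#' Fit a binomial logistic suitability model
#'
#' Maximum-likelihood logistic regression of presence (1) versus
#' pseudo-absence (0) with linear and quadratic terms of each variable.
#' Predictors are z-scored internally against the pseudo-absence sample;
#' the scaling is stored and replayed at prediction.  Complete or
#' quasi-complete separation triggers a ridge-penalized refit (penalty
#' 1e-6 on the standardized coefficients) with a warning rather than a
#' failure.
#'
#' @param presenceEnv data.frame of environments at presence points.
#' @param pseudoabsenceEnv data.frame of environments at pseudo-absence
#'   points.
#' @return a fitted \linkS4class{NicheModel} (algorithm "glm").
#' @export
fitGlm <- function(presenceEnv, pseudoabsenceEnv) {
  presenceEnv <- as.data.frame(presenceEnv)
  pseudoabsenceEnv <- as.data.frame(pseudoabsenceEnv)
  if (nrow(presenceEnv) < 1L || nrow(pseudoabsenceEnv) < 1L)
    stop("both presence and pseudo-absence sets must be non-empty")
  vars <- names(presenceEnv)
  fa <- quadFeatures(pseudoabsenceEnv, vars = vars)
  Fa <- fa$F
  Fp <- quadFeatures(presenceEnv, scaling = fa$scaling)$F
  X <- rbind(Fp, Fa)
  y <- c(rep(1L, nrow(Fp)), rep(0L, nrow(Fa)))

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- fit$coefficients
  if (separated || anyNA(beta)) {
    warning("separation detected; refitting with a small ridge penalty (1e-6)")
    beta <- ridgeLogistic(cbind(`(Intercept)` = 1, X), y, penalty = 1e-6)
  }
  trainEnv <- rbind(presenceEnv[vars], pseudoabsenceEnv[vars])
  refRanges <- rbind(min = apply(trainEnv, 2, min),
                     max = apply(trainEnv, 2, max))
  new("NicheModel", algorithm = "glm", variables = vars,
      fit = list(coefficients = beta, scaling = fa$scaling,
                 separated = separated, refRanges = refRanges,
                 trainEnv = trainEnv),
      trainingSummary = list(nPresence = nrow(Fp), nContrast = nrow(Fa),
                             contrastMode = "pseudo-absence",
                             settings = list(features = "linear+quadratic")))
}

# ridge-penalized IRLS for binomial logistic regression; the intercept is
# not penalized
ridgeLogistic <- function(X, y, penalty = 1e-6, maxIter = 100L,
                          tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(penalty, p)
  pen[1] <- 0
  beta <- numeric(p)
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    betaNew <- solve(XtW %*% X + diag(pen), XtW %*% z)
    if (max(abs(betaNew - beta)) < tol) {
      beta <- drop(betaNew)
      break
    }
    beta <- drop(betaNew)
  }
  names(beta) <- colnames(X)
  beta
}

#' GLM coefficients on the standardized or original predictor scale
#'
#' The model is fitted on internally standardized linear and quadratic
#' features; \code{scale = "original"} back-transforms the coefficients to
#' the raw-variable parameterization
#' \code{b0 + sum_j (bL_j x_j + bQ_j x_j^2)}, which is the scale on which a
#' data-generating model is usually written.
#'
#' @param model a \linkS4class{NicheModel} with algorithm "glm".
#' @param scale "standardized" (as fitted) or "original".
#' @return named numeric coefficient vector.
#' @export
glmCoefficients <- function(model, scale = c("original", "standardized")) {
  stopifnot(model@algorithm == "glm")
  scale <- match.arg(scale)
  beta <- model@fit$coefficients
  if (scale == "standardized") return(beta)
  sc <- model@fit$scaling
  vars <- sc$vars
  b0 <- beta[["(Intercept)"]]
  out <- c(`(Intercept)` = 0)
  for (v in vars) {
    bL <- beta[[v]]
    bQ <- beta[[paste0(v, "^2")]]
    m <- sc$mu[[v]]; s <- sc$sd[[v]]
    m2 <- sc$mu2[[v]]; s2 <- sc$sd2[[v]]
    a2 <- bQ / (s2 * s^2)                      # coefficient on x^2
    a1 <- bL / s - 2 * m * bQ / (s2 * s^2)     # coefficient on x
    b0 <- b0 - bL * m / s + bQ * (m^2 / s^2 - m2) / s2
    out[[v]] <- a1
    out[[paste0(v, "^2")]] <- a2
  }
  out[["(Intercept)"]] <- b0
  out
}

#' Fit a random-forest suitability model
#'
#' Bagged ensemble of classification trees on presence (1) versus
#' pseudo-absence (0); suitability is the fraction of trees voting
#' presence.  The seed is stored so refits reproduce predictions exactly.
#'
#' @param presenceEnv data.frame of environments at presence points.
#' @param pseudoabsenceEnv data.frame of environments at pseudo-absence
#'   points.
#' @param nTrees number of trees; 500 is the conventional stabilized
#'   choice.
#' @param seed RNG seed for tree growing.
#' @return a fitted \linkS4class{NicheModel} (algorithm "rf").
#' @export
fitRf <- function(presenceEnv, pseudoabsenceEnv, nTrees = 500L, seed = 1L) {
  presenceEnv <- as.data.frame(presenceEnv)
  pseudoabsenceEnv <- as.data.frame(pseudoabsenceEnv)
  if (nrow(presenceEnv) < 1L || nrow(pseudoabsenceEnv) < 1L)
    stop("both presence and pseudo-absence sets must be non-empty")
  if (nTrees < 1L) stop("nTrees must be at least 1")
  vars <- names(presenceEnv)
  X <- rbind(presenceEnv[vars], pseudoabsenceEnv[vars])
  y <- factor(c(rep(1L, nrow(presenceEnv)), rep(0L, nrow(pseudoabsenceEnv))),
              levels = c(0L, 1L))
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y,
                                       ntree = as.integer(nTrees))
  refRanges <- rbind(min = apply(X, 2, min), max = apply(X, 2, max))
  new("NicheModel", algorithm = "rf", variables = vars,
      fit = list(forest = forest, refRanges = refRanges, trainEnv = X,
                 seed = as.integer(seed)),
      trainingSummary = list(nPresence = nrow(presenceEnv),
                             nContrast = nrow(pseudoabsenceEnv),
                             contrastMode = "pseudo-absence",
                             settings = list(nTrees = as.integer(nTrees),
                                             seed = as.integer(seed))))
}

# truncate env columns to the model's training ranges
clampEnv <- function(env, refRanges) {
  env <- as.data.frame(env)
  for (v in colnames(refRanges))
    env[[v]] <- pmin(pmax(env[[v]], refRanges["min", v]),
                     refRanges["max", v])
  env
}

#' @rdname predictSuitability
#' @export
setMethod("predictSuitability", "NicheModel", function(model, env,
                                                       clamp = TRUE) {
  env <- as.data.frame(env)
  missing <- setdiff(model@variables, names(env))
  if (length(missing))
    stop(sprintf("environment lacks model variable(s): %s",
                 paste(missing, collapse = ", ")))
  env <- env[model@variables]
  if (clamp) env <- clampEnv(env, model@fit$refRanges)
  out <- switch(model@algorithm,
    maxent = predictMaxent(model, env),
    glm = {
      F_ <- quadFeatures(env, scaling = model@fit$scaling,
                         vars = model@variables)$F
      stats::plogis(drop(cbind(1, F_) %*% model@fit$coefficients))
    },
    rf = {
      p <- stats::predict(model@fit$forest, newdata = env, type = "prob")
      unname(p[, "1"])
    })
  pmin(pmax(out, 0), 1)
})

#' Predict a suitability surface over a climate grid
#'
#' Applies the model cell-by-cell on valid cells; nodata is propagated.
#' With \code{clamp = TRUE} (default) the environment is truncated to the
#' model's training ranges first, the conventional behavior when
#' transferring models to novel climates.
#'
#' @param model a fitted \linkS4class{NicheModel}.
#' @param grid a \linkS4class{ClimateGrid} carrying all model variables.
#' @param speciesId species label to stamp on the map.
#' @param clamp logical; clamp the environment to the training range.
#' @return a \linkS4class{SuitabilityMap} at the grid's age.
#' @export
predictMap <- function(model, grid, speciesId = NA_character_,
                       clamp = TRUE) {
  missing <- setdiff(model@variables, varNames(grid))
  if (length(missing))
    stop(sprintf("grid lacks model variable(s): %s",
                 paste(missing, collapse = ", ")))
  valid <- as.vector(grid@mask)
  env <- as.data.frame(gridEnvMatrix(grid))[valid, model@variables,
                                            drop = FALSE]
  vals <- rep(NA_real_, length(valid))
  vals[valid] <- predictSuitability(model, env, clamp = clamp)
  new("SuitabilityMap",
      values = matrix(vals, nrow(grid@mask), ncol(grid@mask)),
      origin = grid@origin, cellSize = grid@cellSize, age = grid@age,
      speciesId = speciesId, algorithm = model@algorithm)
}
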