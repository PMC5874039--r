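# Hindcasting across the paleoclimate stack and non-analogue climate
# diagnostics (clamping, MESS, MoD).

#' Hindcast a fitted model across a climate stack
#'
#' Predicts one suitability map per requested age by applying the model to
#' each slice (with training-range clamping by default).  Output order
#' follows the \code{ages} argument.
#'
#' @param model a fitted \linkS4class{NicheModel}.
#' @param stack a \linkS4class{ClimateStack}.
#' @param ages kyr BP ages to project to; all must be present in the stack.
#' @param speciesId species label to stamp on the maps.
#' @param clamp logical; clamp each slice's environment to the model's
#'   training ranges (default TRUE).
#' @return list of \linkS4class{SuitabilityMap}, one per age.
#' @export
hindcast <- function(model, stack, ages, speciesId = NA_character_,
                     clamp = TRUE) {
  avail <- ages(stack)
  miss <- setdiff(as.integer(ages), avail)
  if (length(miss))
    stop(sprintf("slice(s) %s not in the stack; available: %s",
                 paste(miss, collapse = ", "),
                 paste(avail, collapse = ", ")))
  out <- lapply(as.integer(ages), function(a)
    predictMap(model, getSlice(stack, a), speciesId = speciesId,
               clamp = clamp))
  names(out) <- as.character(as.integer(ages))
  out
}

# piecewise similarity for one variable; ref is the reference sample
messSimilarity <- function(ref, v) {
  n <- length(ref)
  rmin <- min(ref)
  rmax <- max(ref)
  f <- 100 * vapply(v, function(x) sum(ref < x), numeric(1)) / n
  if (rmax == rmin) {
    out <- ifelse(v == rmin, 100, -Inf)
    if (any(is.infinite(out)))
      warning("constant reference variable with values outside it; similarity set to -Inf")
    return(out)
  }
  out <- numeric(length(v))
  i0 <- f == 0
  i100 <- f == 100
  ilo <- f > 0 & f <= 50
  ihi <- f > 50 & f < 100
  out[i0] <- (v[i0] - rmin) / (rmax - rmin) * 100
  out[ilo] <- 2 * f[ilo]
  out[ihi] <- 2 * (100 - f[ihi])
  out[i100] <- (rmax - v[i100]) / (rmax - rmin) * 100
  out
}

#' Multivariate environmental similarity surface (MESS) and MoD
#'
#' For each cell and variable, the similarity of the cell's value to the
#' reference sample is computed from the percent f of reference values
#' strictly below it: \code{(v-min)/(max-min)*100} when f = 0, \code{2f}
#' when 0 < f <= 50, \code{2(100-f)} when 50 < f < 100, and
#' \code{(max-v)/(max-min)*100} when f = 100.  MESS is the minimum over
#' variables (negative exactly where some variable lies outside the
#' reference range); MoD is the index of the minimizing variable (lowest
#' index on ties).  The clamping mask marks cells where any variable falls
#' outside the reference range.
#'
#' @param referenceEnv data.frame of reference environments (typically the
#'   model's training presences plus background).
#' @param grid the projection \linkS4class{ClimateGrid}.
#' @return a \linkS4class{MessResult}.
#' @export
mess <- function(referenceEnv, grid) {
  referenceEnv <- as.data.frame(referenceEnv)
  vars <- names(referenceEnv)
  miss <- setdiff(vars, varNames(grid))
  if (length(miss))
    stop(sprintf("grid lacks reference variable(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(referenceEnv) < 1L) stop("reference environment is empty")
  dm <- dim(grid@mask)
  valid <- as.vector(grid@mask)
  sims <- matrix(NA_real_, sum(valid), length(vars))
  refRanges <- rbind(min = vapply(referenceEnv, min, numeric(1)),
                     max = vapply(referenceEnv, max, numeric(1)))
  colnames(refRanges) <- vars
  outside <- rep(FALSE, sum(valid))
  for (j in seq_along(vars)) {
    v <- as.vector(grid@variables[[vars[j]]])[valid]
    sims[, j] <- messSimilarity(referenceEnv[[vars[j]]], v)
    outside <- outside | v < refRanges["min", j] | v > refRanges["max", j]
  }
  messVec <- apply(sims, 1, min)
  modVec <- apply(sims, 1, which.min)   # lowest index on ties
  toGrid <- function(x, mode_) {
    full <- rep(if (mode_ == "int") NA_integer_ else NA_real_, length(valid))
    full[valid] <- x
    matrix(full, dm[1], dm[2])
  }
  new("MessResult",
      mess = toGrid(messVec, "dbl"),
      mod = toGrid(as.integer(modVec), "int"),
      clampingMask = {
        full <- rep(NA, length(valid))
        full[valid] <- outside
        matrix(full, dm[1], dm[2])
      },
      referenceRanges = refRanges)
}

#' Clamp a climate grid to reference ranges
#'
#' Values below/above the per-variable reference minimum/maximum are
#' replaced by that bound.  The valid/nodata status of cells is unchanged.
#'
#' @param grid a \linkS4class{ClimateGrid}.
#' @param refRanges numeric matrix with rows "min"/"max" and one column per
#'   variable to clamp (must cover all model variables when used for
#'   prediction).
#' @return list with \code{grid} (the clamped \linkS4class{ClimateGrid})
#'   and \code{mask} (logical matrix, TRUE where any variable changed).
#' @export
clampGrid <- function(grid, refRanges) {
  vars <- colnames(refRanges)
  miss <- setdiff(vars, varNames(grid))
  if (length(miss))
    stop(sprintf("grid lacks variable(s): %s", paste(miss, collapse = ", ")))
  changed <- matrix(FALSE, nrow(grid@mask), ncol(grid@mask))
  out <- grid
  for (v in vars) {
    m <- grid@variables[[v]]
    cl <- pmin(pmax(m, refRanges["min", v]), refRanges["max", v])
    changed <- changed | (!is.na(m) & cl != m)
    out@variables[[v]] <- cl
  }
  list(grid = out, mask = changed)
}
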