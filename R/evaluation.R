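# Cross-validated model accuracy (AUC, TSS) and inter-algorithm map
# agreement.

#' Area under the ROC curve (exact rank statistic)
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen absence, with ties counted one half (the Mann-Whitney
#' formulation).  Exact, not a trapezoid approximation.
#'
#' @param presenceScores scores at presence (test) points.
#' @param absenceScores scores at absence/background (test) points.
#' @return AUC in [0, 1].
#' @export
auc <- function(presenceScores, absenceScores) {
  np <- length(presenceScores)
  na_ <- length(absenceScores)
  if (np < 1L || na_ < 1L)
    stop("both score lists must be non-empty")
  r <- rank(c(presenceScores, absenceScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na_)
}

#' True skill statistic at the optimal threshold
#'
#' TSS(t) = sensitivity(t) + specificity(t) - 1, where a score counts as a
#' predicted presence when it is at least t.  The statistic is maximized
#' over all distinct observed scores plus the midpoints between consecutive
#' distinct scores; the smallest maximizing threshold is reported.
#'
#' @param presenceScores scores at presence (test) points.
#' @param absenceScores scores at absence (test) points.
#' @return list with \code{tss} (in [-1, 1]) and \code{threshold}.
#' @export
tss <- function(presenceScores, absenceScores) {
  if (length(presenceScores) < 1L || length(absenceScores) < 1L)
    stop("both score lists must be non-empty")
  s <- sort(unique(c(presenceScores, absenceScores)))
  cand <- sort(unique(c(s, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2)))
  vals <- vapply(cand, function(t) {
    sens <- mean(presenceScores >= t)
    spec <- mean(absenceScores < t)
    sens + spec - 1
  }, numeric(1))
  best <- max(vals)
  list(tss = best, threshold = cand[which(vals == best)[1L]])
}

#' Repeated-split cross-validation of a suitability model
#'
#' For each repetition, presences and contrast points (background or
#' pseudo-absences, whichever the algorithm is fitted with) are split at
#' random into a training fraction and a held-out test fraction; the model
#' is fitted on the training part, the held-out points are scored, and AUC
#' and TSS are computed.  Repetitions whose fit fails are skipped and
#' counted; more than 20\% skips is an error.
#'
#' @param fitFun function(presenceEnv, contrastEnv) returning a fitted
#'   \linkS4class{NicheModel}.
#' @param presenceEnv data.frame of environments at presence points.
#' @param contrastEnv data.frame of environments at contrast points.
#' @param nReps number of repetitions (conventionally 50).
#' @param splitFraction training fraction (conventionally 0.75).
#' @param seed RNG seed; each repetition derives its own sub-seed.
#' @return an \linkS4class{EvaluationResult}.
#' @export
crossValidate <- function(fitFun, presenceEnv, contrastEnv, nReps = 50L,
                          splitFraction = 0.75, seed = 1L) {
  presenceEnv <- as.data.frame(presenceEnv)
  contrastEnv <- as.data.frame(contrastEnv)
  np <- nrow(presenceEnv)
  nc <- nrow(contrastEnv)
  nTrainP <- floor(np * splitFraction)
  if (np - nTrainP < 1L || nTrainP < 1L)
    stop("too few presences for the requested split")
  nTrainC <- max(1L, floor(nc * splitFraction))
  rows <- vector("list", nReps)
  nSkipped <- 0L
  for (rep_ in seq_len(nReps)) {
    set.seed((as.numeric(seed) * 1000 + rep_) %% 2147483647)
    ip <- sample.int(np, nTrainP)
    ic <- sample.int(nc, nTrainC)
    res <- tryCatch({
      model <- fitFun(presenceEnv[ip, , drop = FALSE],
                      contrastEnv[ic, , drop = FALSE])
      sp <- predictSuitability(model, presenceEnv[-ip, , drop = FALSE])
      sa <- predictSuitability(model, contrastEnv[-ic, , drop = FALSE])
      t_ <- tss(sp, sa)
      data.frame(rep = rep_, auc = auc(sp, sa), tss = t_$tss,
                 threshold = t_$threshold)
    }, error = function(e) NULL)
    if (is.null(res)) nSkipped <- nSkipped + 1L else rows[[rep_]] <- res
  }
  if (nSkipped > 0.2 * nReps)
    stop(sprintf("%d of %d repetitions failed to fit", nSkipped, nReps))
  perRep <- do.call(rbind, rows)
  new("EvaluationResult", perRep = perRep,
      meanAuc = mean(perRep$auc), sdAuc = stats::sd(perRep$auc),
      meanTss = mean(perRep$tss), sdTss = stats::sd(perRep$tss),
      nReps = nrow(perRep), splitFraction = splitFraction,
      seed = as.integer(seed), nSkipped = nSkipped)
}

#' Pearson correlation between two suitability maps
#'
#' Computed over cells valid in both maps; the maps must share geometry.
#'
#' @param mapA,mapB \linkS4class{SuitabilityMap}s on the same grid.
#' @return Pearson r.
#' @export
mapCorrelation <- function(mapA, mapB) {
  if (!identical(dim(mapA@values), dim(mapB@values)) ||
      !isTRUE(all.equal(mapA@origin, mapB@origin)) ||
      !isTRUE(all.equal(mapA@cellSize, mapB@cellSize)))
    stop("maps must share geometry")
  ok <- !is.na(mapA@values) & !is.na(mapB@values)
  if (sum(ok) < 2L)
    stop("fewer than 2 jointly valid cells")
  a <- mapA@values[ok]
  b <- mapB@values[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: a map has zero variance over joint cells")
  stats::cor(a, b)
}
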