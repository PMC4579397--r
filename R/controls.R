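#' Target-discrimination control experiment
#'
#' Tests whether prior knowledge at the drug-target and network level is
#' informative, by training the same evidence three ways and comparing the
#' final population mean scores:
#' \enumerate{
#'   \item the real K/P-S network with the true target(s);
#'   \item randomized networks (enzyme column shuffled) with the true
#'     target(s), averaged over \code{nShuffles} shuffles;
#'   \item the real network with a wrong but \emph{viable} target: an
#'     alternative enzyme that can still reach at least \code{viableReach}
#'     of the enzymes directly targeting the focal perturbed sites, chosen
#'     maximally distant from them at the protein level (a plausible decoy
#'     that explains the sites only through long paths).
#' }
#' A setting whose background construction fails (no path from target to
#' any perturbed site) is assigned the empty-model score, i.e. the full
#' false-negative penalty. With informative knowledge the expected outcome
#' is \code{true < shuffled < wrong}.
#'
#' @param kps K/P-S edge table ([loadKps()]).
#' @param smatrix an \linkS4class{SMatrix}.
#' @param condition focal condition (name in the SMatrix columns) whose
#'   perturbed sites are modelled.
#' @param trueTargets the condition's nominal target id(s).
#' @param params [trainingParams()]; the randomized-network settings are
#'   each trained with a single run.
#' @param nShuffles number of independent enzyme shuffles (default 3).
#' @param viableReach minimal fraction of focal-site enzymes a wrong-target
#'   candidate must reach (default 0.8); an error is raised when no
#'   candidate qualifies, in which case the discrimination experiment is
#'   not well-posed for this network.
#' @param limits,evidence passed to [buildBackground()].
#' @param seed integer seed.
#' @return list: \code{scores} (named numeric: true, shuffled, wrong),
#'   \code{wrongTarget}, \code{shuffleScores}, \code{emptyScore}.
#' @export
targetControlExperiment <- function(kps, smatrix, condition, trueTargets,
                                    params = trainingParams(
                                      n = 500L, generations = 20L,
                                      nRuns = 3L, cap = 20, tolBest = 0.15,
                                      sizeP = 0),
                                    nShuffles = 3L, viableReach = 0.8,
                                    limits = pathLimits(),
                                    evidence = "all", seed = 1L) {
  stopifnot(is(smatrix, "SMatrix"),
            condition %in% colnames(siteScores(smatrix)))
  SS <- siteScores(smatrix)
  pert <- rownames(SS)[smatrix@sitePerturbed[, condition]]
  if (!length(pert)) stop("no perturbed site under condition ", condition)
  emptyScore <- sum(pmax(-SS[, condition], 0))

  # wrong-but-viable decoy: reaches the focal sites' enzymes, but from far
  pg <- proteinProjection(kps)
  kpd <- intersect(unique(kps$enzyme[kps$site %in% pert]),
                   igraph::V(pg)$name)
  cand <- setdiff(intersect(unique(kps$enzyme), igraph::V(pg)$name),
                  trueTargets)
  D <- igraph::distances(pg, v = cand, to = kpd, mode = "out")
  reach <- rowMeans(is.finite(D))
  viable <- cand[reach >= viableReach]
  if (!length(viable))
    stop("no viable alternative target (max reach ",
         round(max(reach), 2), "): experiment not well-posed")
  meanDist <- apply(D[viable, , drop = FALSE], 1, function(z)
    mean(z[is.finite(z)]))
  wrongTarget <- viable[which.max(meanDist)]

  panel <- stats::setNames(list(NULL), condition)
  fitOne <- function(kpsX, tg, params1, seed1) {
    bg <- tryCatch(
      suppressMessages(buildBackground(kpsX, targets = tg,
                                       perturbed = pert, limits = limits,
                                       evidence = evidence)),
      error = function(e) NULL)
    if (is.null(bg)) return(emptyScore)
    panel[[condition]] <- tg
    tr <- trainModels(bg, smatrix, panel, params1, seed = seed1)
    mean(vapply(tr$runs, function(r)
      utils::tail(r@trajectory$mean, 1), numeric(1)))
  }
  seeds <- deriveSeeds(seed, 2L + nShuffles)
  sTrue <- fitOne(kps, trueTargets, params, seeds[1])
  sWrong <- fitOne(kps, wrongTarget, params, seeds[2])
  p1 <- params; p1$nRuns <- 1L
  set.seed(seeds[3])
  shufScores <- vapply(seq_len(nShuffles), function(i)
    fitOne(randomizeKps(kps), trueTargets, p1, seeds[2L + i]), numeric(1))
  list(scores = c(true = sTrue, shuffled = mean(shufScores),
                  wrong = sWrong),
       wrongTarget = wrongTarget, shuffleScores = shufScores,
       emptyScore = emptyScore)
}
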