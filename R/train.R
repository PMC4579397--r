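#' Training parameters
#'
#' Defaults follow the published proof-of-principle settings: populations of
#' 5,000 models per generation, weight cap 5, 30\% best-family tolerance,
#' size penalty on, 50 generations, three independent runs combined, 20\%
#' consensus tolerance. (The alternative published setting uses sizeP = 0,
#' tolerance 15\% and cap 20.)
#'
#' @param n models sampled per generation.
#' @param cap weight-correction ceiling (virtual copies per unit frequency).
#' @param tolBest best-family tolerance: models scoring within
#'   \code{tolBest * |best|} of the best score are selected.
#' @param generations generation cap.
#' @param sizeP additive per-selected-edge model-size penalty weight.
#' @param nRuns independent optimizations to combine.
#' @param consensusTol consensus-network tolerance.
#' @param interInit initial inclusion probability rule for intermediate
#'   nodes (see [initialWeights()]).
#' @param compound if TRUE, weight-correction counts accumulate across
#'   generations instead of being recomputed from each generation's
#'   best-family frequencies.
#' @param scoreTol,freqTol,stableGens convergence rule: training stops once
#'   the population mean score moves by less than \code{scoreTol * |best|}
#'   and every edge frequency by less than \code{freqTol} for
#'   \code{stableGens} consecutive generations.
#' @return list of parameters.
#' @export
trainingParams <- function(n = 5000L, cap = 5, tolBest = 0.30,
                           generations = 50L, sizeP = 1, nRuns = 3L,
                           consensusTol = 0.20,
                           interInit = c("half", "inverse"),
                           compound = FALSE, scoreTol = 0.01,
                           freqTol = 0.01, stableGens = 3L) {
  stopifnot(n >= 1L, cap >= 0, tolBest >= 0, tolBest <= 1,
            consensusTol >= 0, consensusTol <= 1, generations >= 1L)
  list(n = as.integer(n), cap = cap, tolBest = tolBest,
       generations = as.integer(generations), sizeP = sizeP,
       nRuns = as.integer(nRuns), consensusTol = consensusTol,
       interInit = match.arg(interInit), compound = isTRUE(compound),
       scoreTol = scoreTol, freqTol = freqTol,
       stableGens = as.integer(stableGens))
}

#' Score one logic model against the evidence matrix
#'
#' The model is simulated once per distinct target set of the panel; for
#' every data condition j mapped to that target set and every measured site
#' i, a predicted-perturbed site contributes its summed evidence score
#' \eqn{S_{ij}} (a true positive when negative, a false positive when
#' positive), and a missed perturbation (not predicted, \eqn{S_{ij} < 0})
#' contributes \eqn{-S_{ij}}. True negatives contribute nothing. Measured
#' sites absent from the model's network are never predicted; sites
#' predicted but never measured are ignored. Lower scores are better.
#'
#' @param model a \linkS4class{LogicModel}.
#' @param smatrix an \linkS4class{SMatrix}.
#' @param panel named list: condition -> target ids.
#' @param sizeP per-selected-edge size penalty weight (default 0).
#' @return list: \code{score}, \code{TP}, \code{FP}, \code{FN} (summed
#'   contributions), \code{sizePenalty}, \code{nEdges} and the
#'   \code{perCondition} decomposition.
#' @export
scoreModel <- function(model, smatrix, panel, sizeP = 0) {
  stopifnot(is(model, "LogicModel"), is(smatrix, "SMatrix"))
  SS <- siteScores(smatrix)
  conds <- intersect(names(panel), colnames(SS))
  if (!length(conds)) stop("no panel condition present in the SMatrix")
  preds <- suppressWarnings(
    predictConditions(model, panel[conds], sites = rownames(SS)))
  per <- do.call(rbind, lapply(conds, function(j) {
    if (is.null(preds[[j]])) return(NULL)
    s <- SS[, j]
    hit <- rownames(SS) %in% preds[[j]]
    data.frame(condition = j,
               TP = sum(s[hit & s < 0]), FP = sum(s[hit & s >= 0]),
               FN = sum(-s[!hit & s < 0]))
  }))
  nEdges <- sum(vapply(model@assignments, function(a)
    length(a$sources), numeric(1)))
  sc <- sum(per$TP) + sum(per$FP) + sum(per$FN) + sizeP * nEdges
  list(score = sc, TP = sum(per$TP), FP = sum(per$FP), FN = sum(per$FN),
       sizePenalty = sizeP * nEdges, nEdges = nEdges, perCondition = per)
}

#' Select the best-scoring family of models
#'
#' Returns the indices of all models scoring within
#' \code{tolBest * |best score|} of the best (minimum) score.
#'
#' @param scores numeric vector of model scores (lower is better).
#' @param tolBest tolerance fraction.
#' @return integer indices of the best family.
#' @export
selectBest <- function(scores, tolBest) {
  stopifnot(length(scores) >= 1L, tolBest >= 0)
  s_star <- min(scores)
  which(scores <= s_star + tolBest * abs(s_star))
}

# Frequencies of inputs within a subset of a sampled population.
# combos = TRUE additionally tabulates exact realized combinations for
# intermediate nodes (needed for consensus extraction / recovery).
populationFrequencies <- function(pop, weights, subset = seq_len(pop$n),
                                  combos = TRUE) {
  lapply(weights@nodes, function(spec) {
    d <- pop$draws[[spec$node]]
    out <- list(role = spec$role, sources = spec$sources)
    ns <- length(subset)
    if (spec$role %in% c("sink", "integrator")) {
      f <- tabulate(d$idx[subset], nbins = nrow(spec$combos)) / ns
      keys <- mapply(function(s, g)
        comboKey(if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]]
                 else character(0), g),
        spec$combos$sources, spec$combos$gate)
      out$combo <- stats::setNames(f, keys)
      edge <- vapply(seq_along(spec$sources), function(e) {
        has <- vapply(strsplit(spec$combos$sources, ";", fixed = TRUE),
                      function(s) spec$sources[e] %in% s, logical(1))
        sum(f[has])
      }, numeric(1))
      out$edge <- stats::setNames(edge, spec$sources)
      out$gateAND <- sum(f[spec$combos$gate == "AND"])
    } else {
      incl <- pop$draws[[spec$node]]$incl[subset, , drop = FALSE]
      out$edge <- stats::setNames(colMeans(incl), spec$sources)
      multi <- rowSums(incl) >= 2L
      gAND <- d$gateAND[subset]
      out$gateAND <- if (any(multi)) mean(gAND[multi]) else NA_real_
      if (combos) {
        key <- vapply(seq_len(nrow(incl)), function(i) {
          src <- spec$sources[incl[i, ]]
          gate <- if (length(src) == 0L) "NONE"
                  else if (length(src) == 1L) "SINGLE"
                  else if (gAND[i]) "AND" else "OR"
          comboKey(src, gate)
        }, character(1))
        tab <- table(key) / ns
        out$combo <- stats::setNames(as.numeric(tab), names(tab))
      }
    }
    out
  })
}

#' Capped weight correction
#'
#' Re-derives the sampling weights from the input frequencies observed in
#' the best-family models: every input receives \code{1 + freq * cap}
#' virtual copies (so \code{cap = 0} restores the uniform initial bins).
#' Categorical (sink/integrator) probabilities are the normalized copy
#' counts over the node's combinations; intermediate per-edge inclusion
#' probabilities are the normalized per-edge counts; the AND-gate
#' probability is averaged with its frequency among multi-edge best models.
#'
#' @param weights current \linkS4class{SamplingWeights}.
#' @param freqs best-family frequencies (as produced internally during
#'   training; per node: \code{combo}, \code{edge}, \code{gateAND}).
#' @param cap weight ceiling (>= 0).
#' @param compound accumulate counts across generations instead of
#'   recomputing from 1 (default FALSE, which reproduces the published
#'   worked examples).
#' @return updated \linkS4class{SamplingWeights}.
#' @export
updateWeights <- function(weights, freqs, cap, compound = FALSE) {
  stopifnot(is(weights, "SamplingWeights"), cap >= 0)
  nodes <- lapply(weights@nodes, function(spec) {
    fr <- freqs[[spec$node]]
    if (is.null(fr)) return(spec)
    if (spec$role %in% c("sink", "integrator")) {
      base <- if (compound) spec$counts else rep(1, length(spec$counts))
      keys <- mapply(function(s, g)
        comboKey(if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]]
                 else character(0), g),
        spec$combos$sources, spec$combos$gate)
      f <- fr$combo[keys]
      f[is.na(f)] <- 0
      spec$counts <- base + unname(f) * cap
    } else {
      base <- if (compound) spec$pEdge * length(spec$sources) else
        rep(1, length(spec$sources))
      cnt <- base + fr$edge[spec$sources] * cap
      spec$pEdge <- unname(cnt / sum(cnt))
      if (is.finite(fr$gateAND))
        spec$pAnd <- (spec$pAnd + fr$gateAND) / 2
    }
    spec
  })
  new("SamplingWeights", nodes = nodes)
}

# Precompute the scoring pieces shared by all generations:
# per condition, score(model) = base + P %*% w with w = S + max(-S, 0).
prepScoring <- function(smatrix, panel, prep) {
  SS <- siteScores(smatrix)
  conds <- intersect(names(panel), colnames(SS))
  if (!length(conds))
    stop("no panel condition present in the SMatrix")
  known <- prep$ids
  usable <- vapply(panel[conds], function(tg)
    any(tg %in% known), logical(1))
  if (any(!usable))
    warning("condition(s) with no in-network target excluded from scoring: ",
            paste(conds[!usable], collapse = ", "))
  conds <- conds[usable]
  if (!length(conds)) stop("no scoreable condition left")
  sig <- vapply(panel[conds], function(tg)
    paste(sort(intersect(tg, known)), collapse = "+"), character(1))
  sitesInNet <- intersect(rownames(SS), known)
  groups <- lapply(unique(sig), function(s) {
    cs <- conds[sig == s]
    Sg <- SS[, cs, drop = FALSE]
    w <- ifelse(Sg < 0, 2 * Sg, Sg)  # effect of predicting site perturbed
    list(targets = intersect(panel[[cs[1]]], known),
         conditions = cs,
         w = rowSums(w[sitesInNet, , drop = FALSE]),
         base = sum(pmax(-Sg, 0)))
  })
  list(groups = groups, sites = sitesInNet, conditions = conds)
}

scorePopulationOnce <- function(pop, prep, sc, sizeP) {
  total <- numeric(pop$n)
  for (g in sc$groups) {
    st <- simulatePopulation(pop, prep, g$targets)
    P <- st[, sc$sites, drop = FALSE]
    total <- total + as.numeric(P %*% g$w) + g$base
  }
  if (sizeP != 0) total <- total + sizeP * populationSizes(pop, prep)
  total
}

#' Run one iterative training optimization
#'
#' Per generation: sample \code{params$n} models from the current weights,
#' simulate each under every distinct target set, score against the evidence
#' matrix, select the best family, and apply the capped weight correction.
#' Training stops when the population mean score and all edge sampling
#' frequencies have stabilized for \code{params$stableGens} consecutive
#' generations, or at the generation cap. The result records the score
#' trajectory and the input frequencies in the final sampled population.
#'
#' @param background a \linkS4class{BackgroundNetwork} with at least one
#'   reachable data site.
#' @param smatrix an \linkS4class{SMatrix}.
#' @param panel named list: condition -> target ids.
#' @param params a [trainingParams()] list.
#' @param seed integer RNG seed for this run.
#' @return a \linkS4class{TrainingResult}.
#' @export
trainRun <- function(background, smatrix, panel, params = trainingParams(),
                     seed = 1L) {
  stopifnot(is(background, "BackgroundNetwork"))
  if (!any(nodeTable(background)$kind == "data_site"))
    stop("refusing to train: background has no reachable data site")
  set.seed(as.integer(seed))
  weights <- initialWeights(background, params$interInit)
  prep <- prepSimulation(weights, background)
  sc <- prepScoring(smatrix, panel, prep)

  traj <- data.frame(generation = integer(), mean = numeric(),
                     best = numeric(), family = integer())
  prevEdge <- NULL
  prevMean <- NULL
  stable <- 0L
  converged <- NA_integer_
  pop <- NULL
  for (g in seq_len(params$generations)) {
    pop <- samplePopulation(weights, params$n)
    scores <- scorePopulationOnce(pop, prep, sc, params$sizeP)
    best <- selectBest(scores, params$tolBest)
    traj <- rbind(traj, data.frame(generation = g, mean = mean(scores),
                                   best = min(scores),
                                   family = length(best)))
    popEdge <- unlist(lapply(
      populationFrequencies(pop, weights, combos = FALSE), `[[`, "edge"))
    if (!is.null(prevEdge)) {
      dScore <- abs(mean(scores) - prevMean)
      dFreq <- max(abs(popEdge - prevEdge))
      ok <- dScore <= params$scoreTol * max(abs(min(scores)), 1e-8) &&
        dFreq <= params$freqTol
      stable <- if (ok) stable + 1L else 0L
      if (stable >= params$stableGens && is.na(converged)) {
        converged <- g
        break
      }
    }
    prevEdge <- popEdge
    prevMean <- mean(scores)
    bestFreq <- populationFrequencies(pop, weights, best, combos = FALSE)
    weights <- updateWeights(weights, bestFreq, params$cap,
                             compound = params$compound)
  }
  freqs <- populationFrequencies(pop, weights, combos = TRUE)
  new("TrainingResult", trajectory = traj, freqs = freqs,
      converged = converged, params = params, seed = as.integer(seed))
}

#' @export
setMethod("show", "TrainingResult", function(object) {
  tr <- object@trajectory
  cat("TrainingResult:", nrow(tr), "generations (n =", object@params$n,
      "models each)\n")
  cat("  mean score:", round(tr$mean[1], 2), "->",
      round(tr$mean[nrow(tr)], 2), "| best:", round(min(tr$best), 2), "\n")
  cat("  converged:",
      if (is.na(object@converged)) "generation cap reached" else
        paste("generation", object@converged), "\n")
})

#' Train multiple independent runs and combine them
#'
#' Runs \code{params$nRuns} optimizations with sub-seeds derived
#' deterministically from \code{seed} (results do not depend on execution
#' order) and averages their final-population frequencies.
#'
#' @inheritParams trainRun
#' @param seed master seed.
#' @return list with \code{runs} (list of \linkS4class{TrainingResult}) and
#'   \code{freqs} (combined frequencies, see [combineRuns()]).
#' @export
trainModels <- function(background, smatrix, panel,
                        params = trainingParams(), seed = 1L) {
  seeds <- deriveSeeds(seed, params$nRuns)
  runs <- lapply(seeds, function(s)
    trainRun(background, smatrix, panel, params, seed = s))
  list(runs = runs, freqs = combineRuns(runs))
}

#' Average final-population frequencies across runs
#'
#' @param runs list of \linkS4class{TrainingResult} objects trained on the
#'   same background with the same parameters.
#' @return combined frequency list (arithmetic mean per node and input).
#' @export
combineRuns <- function(runs) {
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, is, logical(1), "TrainingResult")))
  ref <- runs[[1]]@freqs
  for (r in runs[-1])
    if (!identical(names(r@freqs), names(ref)))
      stop("runs trained on different backgrounds cannot be combined")
  lapply(names(ref), function(v) NULL) -> out
  names(out) <- names(ref)
  avg <- function(v, what, keys) {
    m <- vapply(runs, function(r) {
      f <- r@freqs[[v]][[what]][keys]
      f[is.na(f)] <- 0
      f
    }, numeric(length(keys)))
    m <- matrix(m, nrow = length(keys))
    stats::setNames(rowMeans(m), keys)
  }
  for (v in names(ref)) {
    fr <- ref[[v]]
    keys <- unique(unlist(lapply(runs, function(r)
      names(r@freqs[[v]]$combo))))
    combo <- avg(v, "combo", keys)
    edge <- avg(v, "edge", fr$sources)
    gA <- vapply(runs, function(r) r@freqs[[v]]$gateAND, numeric(1))
    out[[v]] <- list(role = fr$role, sources = fr$sources, combo = combo,
                     edge = edge,
                     gateAND = if (all(is.na(gA))) NA_real_ else
                       mean(gA, na.rm = TRUE))
  }
  out
}

#' Extract the consensus network from combined frequencies
#'
#' With \code{tol = 0} this is the majority-voting model: each node keeps
#' its maximum-frequency input combination (ties broken deterministically by
#' node id then combination key). With \code{tol > 0}, every combination
#' with frequency at least \code{(1 - tol)} times the node's maximum is
#' retained; edge attributes carry the (run-averaged) per-edge frequencies.
#'
#' @param freqs combined frequencies from [combineRuns()] or a single run's
#'   \code{freqs} slot.
#' @param background the \linkS4class{BackgroundNetwork} trained on.
#' @param tol consensus tolerance in [0, 1].
#' @return a \linkS4class{ConsensusNetwork}.
#' @export
consensusNetwork <- function(freqs, background, tol = 0.20) {
  stopifnot(tol >= 0, tol <= 1, is(background, "BackgroundNetwork"))
  ek <- edgeTable(background)
  ekind <- stats::setNames(ek$kind, paste(ek$source, ek$target))
  rows <- list()
  for (v in sort(names(freqs))) {
    fr <- freqs[[v]]
    f <- fr$combo
    f <- f[order(names(f))]  # deterministic tie-break by combination key
    if (!length(f) || max(f) <= 0) {
      warning("node with all-zero input frequencies omitted: ", v)
      next
    }
    keep <- if (tol == 0) names(f)[which.max(f)] else
      names(f)[f >= (1 - tol) * max(f)]
    srcs <- unique(unlist(lapply(keep, function(k) {
      if (k == "NONE") return(character(0))
      strsplit(sub("^[A-Z]+:", "", k), "+", fixed = TRUE)[[1]]
    })))
    if (!length(srcs)) next
    rows[[v]] <- data.frame(
      source = srcs, target = v,
      kind = unname(ekind[paste(srcs, v)]), node = v,
      frequency = unname(fr$edge[srcs]), stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               kind = character(), node = character(),
               frequency = numeric())
  rownames(edges) <- NULL
  nt <- nodeTable(background)
  ids <- unique(c(edges$source, edges$target, background@targets))
  nodes <- nt[nt$id %in% ids, c("id", "kind"), drop = FALSE]
  rownames(nodes) <- NULL
  new("ConsensusNetwork", edges = edges, nodes = nodes, tol = tol)
}

#' @export
setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (tolerance", object@tol, ")\n")
})
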