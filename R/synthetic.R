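#' Generate a ground-truth signalling network and logic model
#'
#' Builds a random kinase/phosphatase-substrate resource with the structure
#' the pipeline assumes: \code{nSites} phosphosites, each hosted on a kinase
#' (with probability \code{fracKinaseHost}, making it a potential relay) or
#' on a substrate-only protein (making it a terminal site), and each drawing
#' 1 to \code{maxKinPerSite} candidate upstream kinases. Cycles are allowed,
#' as in real kinase networks. A planted logic model is drawn from the
#' initial sampling distribution over the full site-level network, a drug
#' panel assigns one distinct target kinase per condition, and the sites
#' each drug perturbs are obtained by simulating the planted model. Drawing
#' is retried (bounded) until every drug perturbs at least one site.
#'
#' @param nKp number of kinases (>= 2).
#' @param nSites number of measured phosphosites (>= 1).
#' @param nDrugs number of drug conditions.
#' @param maxKinPerSite maximal candidate kinases per site (default 5).
#' @param fracKinaseHost probability a site lives on a kinase (default 0.25,
#'   matching the minority of phosphosites that sit on kinases/phosphatases
#'   themselves in curated resources).
#' @param truthStyle how the planted model is drawn. \code{"single"}
#'   (default): every non-root node receives one input chosen uniformly
#'   among its candidates, reflecting the dominant-kinase regulation that
#'   single-perturbation designs can identify. \code{"sampler"}: drawn from
#'   the untrained sampling distribution, which also plants inactive (NONE)
#'   nodes and multi-input gates that single perturbations cannot
#'   discriminate.
#' @param minSitesPerDrug the planted model is redrawn (bounded retries)
#'   until every drug perturbs at least this many sites (default 5, 10\% of
#'   the default site count): the benchmark emulates inhibitors with a
#'   clearly detectable footprint, the regime in which network training is
#'   meaningful.
#' @param delta planted log2 shift of perturbed sites (default 5; inhibition
#'   decreases phosphorylation, so the applied shift is \code{-delta}).
#' @param sigma total replicate noise sd in log2 units (default 0.3);
#'   split as biological sd = 2 x technical sd.
#' @param seed integer seed; fixed seed gives identical truth.
#' @return a \linkS4class{GroundTruth}.
#' @export
generateTruth <- function(nKp = 20L, nSites = 50L, nDrugs = 4L,
                          maxKinPerSite = 5L, fracKinaseHost = 0.25,
                          truthStyle = c("single", "sampler"),
                          minSitesPerDrug = 5L, delta = 5, sigma = 0.3,
                          seed = 1L) {
  stopifnot(nKp >= 2L, nSites >= 1L, nDrugs >= 1L, nDrugs <= nKp,
            delta > 0, sigma > 0)
  truthStyle <- match.arg(truthStyle)
  set.seed(as.integer(seed))
  kinases <- sprintf("KP%02d", seq_len(nKp))
  nSub <- max(2L, ceiling(nSites / 4))
  subs <- sprintf("SUB%02d", seq_len(nSub))

  for (graphTry in 1:10) {
    hostKin <- stats::runif(nSites) < fracKinaseHost
    host <- ifelse(hostKin, sample(kinases, nSites, replace = TRUE),
                   sample(subs, nSites, replace = TRUE))
    residue <- sample(c("S", "T", "Y"), nSites, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
    position <- integer(nSites)
    for (h in unique(host)) {
      i <- which(host == h)
      position[i] <- sort(sample(1:999, length(i)))
    }
    sites <- data.frame(site = paste0(host, ".", residue, position),
                        host = host, residue = residue, position = position,
                        stringsAsFactors = FALSE)
    kps <- do.call(rbind, lapply(seq_len(nSites), function(i) {
      cand <- sample(setdiff(kinases, host[i]),
                     sample.int(maxKinPerSite, 1L))
      data.frame(enzyme = cand, substrate = host[i], residue = residue[i],
                 position = position[i],
                 evidence = ifelse(stats::runif(length(cand)) < 0.7,
                                   "experimental", "predicted"),
                 motif_score = round(stats::runif(length(cand), 0.5, 1), 3),
                 context_score = round(stats::runif(length(cand), 0.5, 1), 3),
                 source = "synthetic", stringsAsFactors = FALSE)
    }))
    kps$site <- paste0(kps$substrate, ".", kps$residue, kps$position)

    # drug targets are hub enzymes, as in real inhibitor panels
    outdeg <- table(factor(kps$enzyme, levels = kinases))
    wts <- (as.numeric(outdeg) + 1)^2
    targets <- sample(kinases, nDrugs, prob = wts)
    panel <- stats::setNames(as.list(targets), paste0("D", seq_len(nDrugs)))

    net <- .truthNetwork(kps, sites, targets)
    w <- initialWeights(net)
    ok <- FALSE
    floorSites <- max(1L, minSitesPerDrug)
    for (modelTry in 1:200) {
      model <- if (truthStyle == "sampler") sampleModel(w, net) else
        .singleInputModel(w, net)
      pert <- lapply(panel, function(tg) {
        st <- simulateModel(model, targets = tg)
        names(st)[st == 1L & isSiteId(names(st))]
      })
      if (all(lengths(pert) >= floorSites)) { ok <- TRUE; break }
      if (modelTry %% 50L == 0L) { # footprint too small: try other targets
        targets <- sample(kinases, nDrugs, prob = wts)
        panel <- stats::setNames(as.list(targets), names(panel))
        net <- .truthNetwork(kps, sites, targets)
        w <- initialWeights(net)
      }
    }
    if (ok) break
  }
  if (!ok)
    warning("could not plant a model with the requested per-drug ",
            "footprint; using the last draw")
  new("GroundTruth", kps = kps, network = net, trueModel = model,
      panel = panel, sites = sites, perturbedSites = pert,
      delta = delta, sigma = sigma, seed = as.integer(seed))
}

# planted model with one uniformly chosen input per non-root node
.singleInputModel <- function(weights, net) {
  asg <- lapply(weights@nodes, function(spec) {
    src <- spec$sources[sample.int(length(spec$sources), 1L)]
    list(sources = src, gate = "SINGLE")
  })
  new("LogicModel", assignments = asg, targets = net@targets)
}

# full site-level network over a generated K/P-S table: kinase -> site kps
# edges, plus integrator edges for sites hosted on kinases
.truthNetwork <- function(kps, sites, targets) {
  kinases <- sort(unique(kps$enzyme))
  edges <- data.frame(source = kps$enzyme, target = kps$site, kind = "kps",
                      evidence = kps$evidence, stringsAsFactors = FALSE)
  onKin <- sites$host %in% kinases
  if (any(onKin))
    edges <- rbind(edges, data.frame(
      source = sites$site[onKin], target = sites$host[onKin],
      kind = "integrator", evidence = "integrator",
      stringsAsFactors = FALSE))
  edges <- unique(edges)
  ids <- unique(c(kinases, sites$site, edges$source, edges$target))
  kind <- ifelse(ids %in% targets, "target_kp",
          ifelse(isSiteId(ids),
                 ifelse(vapply(ids, function(i)
                   !i %in% edges$source[edges$kind == "integrator"],
                   logical(1)), "data_site", "site"), "kp"))
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE, vertices = ids)
  d <- igraph::distances(g, v = targets, mode = "out")
  d <- if (length(targets) > 1L) apply(d, 2, min) else drop(d)
  d[!is.finite(d)] <- 999
  nodes <- data.frame(id = ids, kind = kind,
                      distance = as.integer(d[ids]),
                      stringsAsFactors = FALSE)
  new("BackgroundNetwork", nodes = nodes, edges = edges, targets = targets,
      limits = pathLimits(), unreachableSites = character(0))
}

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", sum(!isSiteId(object@network@nodes$id)), "proteins,",
      nrow(object@sites), "sites,", length(object@panel), "drugs\n")
  cat("  perturbed sites per drug:",
      paste(names(object@perturbedSites), lengths(object@perturbedSites),
            sep = ": ", collapse = ", "), "\n")
  cat("  delta =", object@delta, "| sigma =", object@sigma, "\n")
})

#' Simulate a replicated intensity screen from a ground truth
#'
#' Emits a \linkS4class{PhosphoSet} with one phosphopeptide per planted
#' site, a control condition and one condition per drug, \code{nBio}
#' biological times \code{nTech} technical replicates. Control log2
#' intensities are drawn around a per-peptide baseline with a biological
#' plus technical noise decomposition (biological sd twice the technical
#' sd); sites perturbed under a condition in the planted model are shifted
#' by \code{-delta} (inhibition decreases phosphorylation), and values are
#' exponentiated back to the intensity scale.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param delta,sigma shift and total noise sd; default from the truth.
#' @param nBio,nTech biological / technical replicates (defaults 2 and 3).
#' @param nBackground additional never-perturbed phosphopeptides on proteins
#'   outside the K/P-S resource (default 400). Discovery screens measure
#'   mostly-unaffected peptides; without this bulk, quantile normalization
#'   would be distorted by the perturbed minority.
#' @param missingRate uniform missing-at-random rate (default 0).
#' @param seed integer seed.
#' @param control name of the control condition (default "CTRL").
#' @return a \linkS4class{PhosphoSet}.
#' @export
simulateDataset <- function(truth, delta = truth@delta,
                            sigma = truth@sigma, nBio = 2L, nTech = 3L,
                            nBackground = 400L, missingRate = 0, seed = 1L,
                            control = "CTRL") {
  stopifnot(is(truth, "GroundTruth"), delta > 0, sigma > 0)
  set.seed(as.integer(seed))
  sites <- truth@sites
  if (nBackground > 0) {
    bg_host <- sprintf("BG%04d", seq_len(nBackground))
    sites <- rbind(sites, data.frame(
      site = paste0(bg_host, ".S1"), host = bg_host,
      residue = "S", position = 1L, stringsAsFactors = FALSE))
  }
  nP <- nrow(sites)
  conds <- c(control, names(truth@panel))
  sigTech <- sigma / sqrt(5)   # sd_bio = 2 sd_tech => sigma^2 = 5 sd_tech^2
  sigBio <- 2 * sigTech

  samples <- expand.grid(tech_rep = seq_len(nTech), bio_rep = seq_len(nBio),
                         condition = conds, stringsAsFactors = FALSE)
  samples$sample <- paste(samples$condition, samples$bio_rep,
                          samples$tech_rep, sep = "_")
  samples$is_control <- samples$condition == control
  samples <- samples[, c("sample", "condition", "bio_rep", "tech_rep",
                         "is_control")]

  shift <- matrix(0, nP, length(conds),
                  dimnames = list(sites$site, conds))
  for (j in names(truth@panel))
    shift[rownames(shift) %in% truth@perturbedSites[[j]], j] <- -delta

  mu <- stats::runif(nP, 18, 28)
  m <- matrix(NA_real_, nP, nrow(samples),
              dimnames = list(NULL, samples$sample))
  for (cc in conds) for (b in seq_len(nBio)) {
    bio <- stats::rnorm(nP, 0, sigBio)
    for (tt in seq_len(nTech)) {
      sm <- paste(cc, b, tt, sep = "_")
      m[, sm] <- mu + shift[, cc] + bio + stats::rnorm(nP, 0, sigTech)
    }
  }
  m <- 2^m
  if (missingRate > 0)
    m[stats::runif(length(m)) < missingRate] <- NA

  peptides <- data.frame(peptide_id = paste0("pep_", sites$site),
                         protein = sites$host,
                         sites = paste0(sites$residue, sites$position),
                         stringsAsFactors = FALSE)
  PhosphoSet(m, peptides, samples)
}

#' Recovery of the planted model from trained frequencies
#'
#' Compares trained input frequencies against the planted logic model on a
#' shared background: per-node top-input accuracy (fraction of sampled
#' nodes whose maximum-frequency input combination recovers the planted
#' one) and precision/recall of the consensus edges against the planted
#' edges.
#'
#' Single-perturbation designs cannot distinguish input combinations that
#' propagate perturbations identically under every assayed condition (for
#' example, two upstream kinases active under exactly the same drugs, or an
#' AND over sites that always co-activate). With
#' \code{equivalence = TRUE} (default) a top input therefore also counts as
#' recovered when substituting it into the planted model leaves the
#' predicted perturbation pattern of every condition unchanged -
#' observational equivalence, the resolution limit of the data. Strict
#' key equality is available with \code{equivalence = FALSE} and reported
#' alongside as \code{strictAccuracy}.
#'
#' @param freqs combined frequencies ([combineRuns()] output or a run's
#'   \code{freqs} slot).
#' @param truth a \linkS4class{GroundTruth}.
#' @param background the trained \linkS4class{BackgroundNetwork}.
#' @param consensusTol tolerance for the consensus edge sets (default 0.2).
#' @param equivalence count observationally equivalent top inputs as
#'   recovered (default TRUE).
#' @return list: \code{accuracy}, \code{strictAccuracy}, \code{precision},
#'   \code{recall}, \code{nNodes} (nodes compared), and the per-node
#'   comparison table.
#' @export
recoveryMetrics <- function(freqs, truth, background, consensusTol = 0.2,
                            equivalence = TRUE) {
  stopifnot(is(truth, "GroundTruth"))
  asg <- truth@trueModel@assignments
  shared <- intersect(names(freqs), names(asg))
  truthPred <- lapply(truth@panel, function(tg) {
    st <- simulateModel(truth@trueModel, targets = tg)
    sort(names(st)[st == 1L])
  })
  sameEffect <- function(v, key) {
    m2 <- truth@trueModel
    src <- if (key == "NONE") character(0) else
      strsplit(sub("^[A-Z]+:", "", key), "+", fixed = TRUE)[[1]]
    m2@assignments[[v]] <- list(sources = src, gate = sub(":.*$", "", key))
    pred <- lapply(truth@panel, function(tg) {
      st <- simulateModel(m2, targets = tg)
      sort(names(st)[st == 1L])
    })
    identical(truthPred, pred)
  }
  perNode <- do.call(rbind, lapply(shared, function(v) {
    f <- freqs[[v]]$combo
    f <- f[order(names(f))]
    top <- if (length(f) && max(f) > 0) names(f)[which.max(f)] else NA
    truthKey <- comboKey(asg[[v]]$sources, asg[[v]]$gate)
    strict <- identical(top, truthKey)
    data.frame(node = v, top = top, truth = truthKey,
               strict = strict,
               correct = strict || (equivalence && !is.na(top) &&
                                      sameEffect(v, top)),
               stringsAsFactors = FALSE)
  }))
  cons <- consensusNetwork(freqs, background, tol = consensusTol)
  consEdges <- unique(paste(cons@edges$source, cons@edges$target))
  truthEdges <- unique(unlist(lapply(shared, function(v) {
    s <- asg[[v]]$sources
    if (length(s)) paste(s, v) else character(0)
  })))
  inter <- intersect(consEdges, truthEdges)
  list(accuracy = mean(perNode$correct),
       strictAccuracy = mean(perNode$strict),
       precision = if (length(consEdges)) length(inter) / length(consEdges)
                   else NA_real_,
       recall = if (length(truthEdges)) length(inter) / length(truthEdges)
                else 0,
       nNodes = nrow(perNode), perNode = perNode)
}

#' Expected top-input accuracy of an untrained sampler
#'
#' Analytic baseline for [recoveryMetrics()]: if a consensus were a single
#' model drawn from the given sampling weights, the probability that a
#' node's drawn combination matches an (independently drawn) planted one is
#' \eqn{\sum_c p_c^2}; the baseline is its mean over sampled nodes.
#'
#' @param weights a \linkS4class{SamplingWeights} (typically
#'   [initialWeights()]).
#' @return numeric scalar.
#' @export
expectedRandomAccuracy <- function(weights) {
  stopifnot(is(weights, "SamplingWeights"))
  mean(vapply(weights@nodes, function(spec) {
    if (spec$role %in% c("sink", "integrator")) {
      p <- spec$counts / sum(spec$counts)
    } else {
      p <- enumerateCombinations(spec$sources, "intermediate",
                                 pEdge = spec$pEdge, pAnd = spec$pAnd)$prob
    }
    sum(p^2)
  }, numeric(1)))
}
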