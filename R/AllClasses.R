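#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' PhosphoSet: container for phosphopeptide intensity screens
#'
#' A \linkS4class{SummarizedExperiment} holding one phosphopeptide ion per row
#' and one MS run per column. Row metadata must carry the peptide identifier,
#' the UniProt id of the host protein and the phosphosite annotation
#' (e.g. \code{"S473"} or \code{"S473;T308"} for multiply phosphorylated
#' peptides). Column metadata must describe the perturbation design:
#' condition, biological replicate, technical replicate, and a control flag.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [PhosphoSet()] for the constructor.
#' @export
setClass("PhosphoSet", contains = "SummarizedExperiment")

.validPhosphoSet <- function(object) {
  msg <- NULL
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  need_rd <- c("peptide_id", "protein", "sites")
  need_cd <- c("condition", "bio_rep", "tech_rep", "is_control")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  if (is.null(msg)) {
    if (anyDuplicated(rd$peptide_id))
      msg <- c(msg, "peptide_id must be unique")
    ctl <- unique(cd$condition[as.logical(cd$is_control)])
    if (length(ctl) != 1L)
      msg <- c(msg, "exactly one condition must be flagged as control")
    a <- SummarizedExperiment::assay(object, 1L)
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative (use NA for missing)")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("PhosphoSet", .validPhosphoSet)

#' Per-condition effect estimates with moderated statistics
#'
#' Holds, for every peptide and non-control condition, the estimated log2
#' fold change versus control together with its moderated standard error,
#' moderated t, raw and Benjamini-Hochberg adjusted p-value, and the number
#' of intensity observations the estimate rests on. The control condition is
#' carried as a zero-effect column so that downstream mixture fits can locate
#' the control population.
#'
#' @slot logFC,se,t,pvalue,padj,nobs matrices (peptide x condition).
#' @slot control name of the control condition.
#' @slot peptides data.frame of peptide annotation (peptide_id, protein, sites).
#' @slot prior list with the empirical-Bayes hyperparameters: \code{df}
#'   (d0), \code{s2} (s0^2) and the per-peptide residual \code{df.residual}
#'   and \code{sigma2}.
#' @export
setClass("EffectResult",
  representation(logFC = "matrix", se = "matrix", t = "matrix",
                 pvalue = "matrix", padj = "matrix", nobs = "matrix",
                 control = "character", peptides = "data.frame",
                 prior = "list"))

setValidity("EffectResult", function(object) {
  dims <- vapply(list(object@se, object@t, object@pvalue, object@padj,
                      object@nobs),
                 function(m) identical(dim(m), dim(object@logFC)), logical(1))
  if (!all(dims)) return("all matrices must share dimensions")
  p <- object@padj[is.finite(object@padj)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("adjusted p-values must lie in [0, 1]")
  TRUE
})

#' Gaussian mixture fit of one peptide's effect profile
#'
#' Result of fitting univariate Gaussian mixtures with 1..9 components to a
#' peptide's per-condition effect estimates and selecting the component count
#' by BIC. For two-component fits the component covering the control effect
#' value is the control population and the other the perturbed population;
#' fits whose two densities overlap too much, or with K != 2, are flagged as
#' not Boolean-compliant and excluded from evidence scoring.
#'
#' @slot peptide peptide identifier.
#' @slot K selected number of components.
#' @slot mean,sd,weight per-component parameters (log2 fold-change units).
#' @slot loglik log-likelihood of the selected model at the final parameters.
#' @slot bic BIC of the selected model, \eqn{-2 \log L + p \ln n} (lower wins).
#' @slot nParams parameter count p used in the BIC penalty.
#' @slot n number of effect values fitted.
#' @slot controlComponent,perturbedComponent component indices (NA if undefined).
#' @slot overlap overlap fraction between the two densities (NA unless K = 2).
#' @slot booleanOk TRUE when K = 2, the control component is defined and the
#'   overlap is at most the threshold.
#' @export
setClass("GmmFit",
  representation(peptide = "character", K = "integer", mean = "numeric",
                 sd = "numeric", weight = "numeric", loglik = "numeric",
                 bic = "numeric", nParams = "integer", n = "integer",
                 controlComponent = "integer", perturbedComponent = "integer",
                 overlap = "numeric", booleanOk = "logical"))

setValidity("GmmFit", function(object) {
  if (length(object@mean) != object@K) return("means must have length K")
  if (abs(sum(object@weight) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@sd <= 0)) return("component sds must be positive")
  TRUE
})

#' Boolean evidence score matrix
#'
#' Per-peptide, per-condition evidence scores S (log10 ratio of control vs
#' perturbed membership probability) with their discrete labels, and the
#' site-level aggregation in which scores of peptides mapping to the same
#' phosphosite are summed as independent pieces of evidence. A site is called
#' perturbed under a condition when its summed S falls below \code{-cut}.
#'
#' @slot S peptide x condition score matrix (NA for non-compliant peptides).
#' @slot label character matrix: "perturbed", "control" or "undetermined".
#' @slot siteS site x condition summed score matrix.
#' @slot sitePerturbed logical matrix of site-level perturbation calls.
#' @slot siteMap data.frame linking peptides to site ids ("UPID.RESPOS").
#' @slot cut the score threshold (default 0.5).
#' @export
setClass("SMatrix",
  representation(S = "matrix", label = "matrix", siteS = "matrix",
                 sitePerturbed = "matrix", siteMap = "data.frame",
                 cut = "numeric"))

#' Background network of candidate signalling paths
#'
#' Directed graph connecting drug-target kinases/phosphatases to perturbed
#' measured phosphosites through knowledge-compatible kinase/phosphatase ->
#' site edges, with integrator edges bridging each relay site to its host
#' protein. Node kinds are \code{target_kp}, \code{kp}, \code{site} (relay)
#' and \code{data_site} (measured, perturbed in at least one condition).
#'
#' @slot nodes data.frame with columns id, kind, distance (BFS distance from
#'   the nearest target, in edges).
#' @slot edges data.frame with columns source, target, kind ("kps" or
#'   "integrator"), evidence.
#' @slot targets character vector of drug-target node ids.
#' @slot limits list with max_target_path and max_site_path (node counts).
#' @slot unreachableSites perturbed sites that no retained enzyme can reach.
#' @export
setClass("BackgroundNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 targets = "character", limits = "list",
                 unreachableSites = "character"))

setValidity("BackgroundNetwork", function(object) {
  if (!all(c("id", "kind") %in% colnames(object@nodes)))
    return("nodes needs id and kind columns")
  if (nrow(object@edges) &&
      !all(c("source", "target", "kind") %in% colnames(object@edges)))
    return("edges needs source, target and kind columns")
  if (nrow(object@edges)) {
    ei <- object@edges[object@edges$kind == "integrator", , drop = FALSE]
    host <- sub("\\.[STY][0-9]+$", "", ei$source)
    if (any(host != ei$target))
      return("integrator edges must connect a site to its own host protein")
  }
  TRUE
})

#' Per-node sampling state of the logic-model search
#'
#' For every non-root node of a background network, the allowed input
#' combinations and the current sampling weights. Sink nodes draw a single
#' upstream enzyme; integrator (protein) nodes draw one site, all sites under
#' an AND, or no input, from a flat categorical; intermediate (relay site)
#' nodes draw each incoming edge independently and then an AND/OR gate.
#'
#' @slot nodes named list; per node: role, sources, combos, weights (counts for
#'   categorical nodes), pEdge, pAnd (intermediate nodes).
#' @export
setClass("SamplingWeights", representation(nodes = "list"))

#' A candidate Boolean logic model
#'
#' One chosen input combination per non-root node of a background network.
#'
#' @slot assignments named list; per node: sources (character) and gate
#'   (one of NONE, SINGLE, AND, OR).
#' @slot targets root nodes, activated directly by the perturbation.
#' @export
setClass("LogicModel",
  representation(assignments = "list", targets = "character"))

#' Result of one training run
#'
#' @slot trajectory data.frame per generation: mean, best (minimum) and
#'   best-family size of the population scores.
#' @slot freqs named list of final-population frequencies per node: combo
#'   (named numeric over input combinations), edge (per incoming edge),
#'   and gateAND.
#' @slot converged generation at which the stopping rule fired (NA if the
#'   generation cap was reached first).
#' @slot params training parameters used.
#' @slot seed RNG seed of this run.
#' @export
setClass("TrainingResult",
  representation(trajectory = "data.frame", freqs = "list",
                 converged = "integer", params = "list", seed = "integer"))

#' Consensus network extracted from combined edge frequencies
#'
#' @slot edges data.frame: source, target, kind, node, frequency.
#' @slot nodes data.frame: id, kind.
#' @slot tol tolerance used (inputs within \code{(1 - tol)} of a node's top
#'   input frequency are retained).
#' @export
setClass("ConsensusNetwork",
  representation(edges = "data.frame", nodes = "data.frame", tol = "numeric"))

#' Planted ground truth for synthetic benchmarks
#'
#' @slot kps generated kinase/phosphatase-substrate table.
#' @slot network full site-level network the truth was drawn from.
#' @slot trueModel the planted \linkS4class{LogicModel}.
#' @slot panel named list: condition -> target ids.
#' @slot sites data.frame of generated sites (site, host, residue, position).
#' @slot perturbedSites named list: condition -> site ids active under the
#'   true model.
#' @slot delta,sigma planted log2 effect shift and total replicate noise sd.
#' @slot seed generator seed.
#' @export
setClass("GroundTruth",
  representation(kps = "data.frame", network = "BackgroundNetwork",
                 trueModel = "LogicModel", panel = "list",
                 sites = "data.frame", perturbedSites = "list",
                 delta = "numeric", sigma = "numeric", seed = "integer"))
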