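#' Path limits for background-network construction
#'
#' Node-count limits for the two path searches of the construction: paths
#' connecting drug targets to each other (up to \code{maxTargetPath} protein
#' nodes, endpoints included) and paths connecting the target component to
#' the enzymes that phosphorylate perturbed sites (up to \code{maxSitePath}
#' protein nodes).
#'
#' @param maxTargetPath default 7.
#' @param maxSitePath default 5.
#' @return list with both limits.
#' @export
pathLimits <- function(maxTargetPath = 7L, maxSitePath = 5L) {
  stopifnot(maxTargetPath >= 1L, maxSitePath >= 1L)
  list(max_target_path = as.integer(maxTargetPath),
       max_site_path = as.integer(maxSitePath))
}

#' Build the dataset-specific background network
#'
#' Constructs the directed graph of knowledge-compatible paths from drug
#' targets to perturbed measured phosphosites:
#' \enumerate{
#'   \item protein-level paths between distinct drug targets, up to
#'     \code{max_target_path} nodes, are retained;
#'   \item the enzymes with a K/P-S edge onto any perturbed site are
#'     collected;
#'   \item protein-level paths from the target component to those enzymes,
#'     up to \code{max_site_path} nodes, are retained;
#'   \item every retained protein-protein step K1 -> K2 is re-expanded to the
#'     site level as K1 -> (site on K2) -> K2, the second hop an integrator
#'     edge;
#'   \item perturbed measured sites are attached as data sites via their
#'     K/P-S edges from retained enzymes.
#' }
#' Nodes unreachable from every target are pruned; perturbed sites that no
#' retained enzyme can reach are reported in the \code{unreachableSites}
#' slot.
#'
#' @param kps K/P-S edge table from [loadKps()].
#' @param targets character vector of drug-target UPIDs (non-empty).
#' @param perturbed character vector of perturbed site ids ("UPID.RESPOS"),
#'   typically [perturbedSites()] of an \linkS4class{SMatrix}.
#' @param limits a [pathLimits()] list.
#' @param evidence \code{"all"} or \code{"experimental_only"}.
#' @param augment optional data.frame of extra edges in the [loadKps()]
#'   schema (e.g. manually curated lipid-kinase links), appended unfiltered.
#' @return a \linkS4class{BackgroundNetwork}.
#' @export
buildBackground <- function(kps, targets, perturbed, limits = pathLimits(),
                            evidence = c("all", "experimental_only"),
                            augment = NULL) {
  evidence <- match.arg(evidence)
  stopifnot(length(targets) >= 1L, nrow(kps) >= 1L)
  targets <- unique(as.character(targets))
  if (evidence == "experimental_only")
    kps <- kps[kps$evidence == "experimental", , drop = FALSE]
  if (!is.null(augment)) {
    augment <- as.data.frame(augment)
    if (!"site" %in% colnames(augment))
      augment$site <- paste0(augment$substrate, ".", augment$residue,
                             augment$position)
    for (cc in setdiff(colnames(kps), colnames(augment)))
      augment[[cc]] <- NA
    kps <- rbind(kps, augment[, colnames(kps), drop = FALSE])
  }
  if (!nrow(kps)) stop("no K/P-S edges left after evidence filtering")

  prot <- proteinProjection(kps)
  missing_t <- setdiff(targets, igraph::V(prot)$name)
  if (length(missing_t)) {
    warning("target(s) absent from the K/P-S network: ",
            paste(missing_t, collapse = ", "))
    prot <- igraph::add_vertices(prot, length(missing_t), name = missing_t)
  }
  vnames <- igraph::V(prot)$name
  pedges <- igraph::as_data_frame(prot, what = "edges")

  keep_v <- structure(logical(length(vnames)), names = vnames)
  keep_e <- logical(nrow(pedges))

  dFrom <- igraph::distances(prot, v = targets, mode = "out")
  dTo <- igraph::distances(prot, v = targets, mode = "in")

  # (1) paths between distinct targets, <= max_target_path nodes
  L1 <- limits$max_target_path - 1L  # edge budget
  if (length(targets) > 1L) {
    for (t1 in targets) for (t2 in setdiff(targets, t1)) {
      dv <- dFrom[t1, ] + dTo[t2, ]
      keep_v <- keep_v | (dv <= L1)
      de <- dFrom[t1, pedges$from] + 1 + dTo[t2, pedges$to]
      keep_e <- keep_e | (de <= L1)
    }
  }
  keep_v[targets] <- TRUE
  targetComponent <- vnames[keep_v]

  # (2) enzymes that directly phosphorylate a perturbed site
  kpd <- unique(kps$enzyme[kps$site %in% perturbed])

  # (3) paths from the target component to those enzymes, <= max_site_path
  if (length(kpd)) {
    L2 <- limits$max_site_path - 1L
    dA <- igraph::distances(prot, v = targetComponent, mode = "out")
    dA <- if (length(targetComponent) > 1L) apply(dA, 2, min) else drop(dA)
    dK <- igraph::distances(prot, v = kpd, mode = "in")
    dK <- if (length(kpd) > 1L) apply(dK, 2, min) else drop(dK)
    keep_v <- keep_v | (dA + dK <= L2)
    keep_e <- keep_e | (dA[pedges$from] + 1 + dK[pedges$to] <= L2)
  }
  Vp <- vnames[keep_v]
  Ep <- pedges[keep_e & pedges$from %in% Vp & pedges$to %in% Vp, ,
               drop = FALSE]

  # (4) site-level expansion of retained protein edges
  exp_idx <- which(kps$enzyme %in% Ep$from & kps$substrate %in% Ep$to)
  exp_idx <- exp_idx[paste(kps$enzyme[exp_idx], kps$substrate[exp_idx]) %in%
                     paste(Ep$from, Ep$to)]
  site_edges <- if (length(exp_idx))
    data.frame(source = kps$enzyme[exp_idx], target = kps$site[exp_idx],
               kind = "kps", evidence = kps$evidence[exp_idx],
               stringsAsFactors = FALSE) else
    data.frame(source = character(), target = character(),
               kind = character(), evidence = character())
  relay_sites <- unique(site_edges$target)
  integ <- if (length(relay_sites))
    data.frame(source = relay_sites, target = siteHost(relay_sites),
               kind = "integrator", evidence = "integrator",
               stringsAsFactors = FALSE) else site_edges[0, ]

  # (5) attach perturbed data sites through their K/P-S edges
  d_idx <- which(kps$site %in% perturbed & kps$enzyme %in% Vp)
  data_edges <- if (length(d_idx))
    data.frame(source = kps$enzyme[d_idx], target = kps$site[d_idx],
               kind = "kps", evidence = kps$evidence[d_idx],
               stringsAsFactors = FALSE) else site_edges[0, ]

  edges <- unique(rbind(site_edges, integ, data_edges))
  if (!nrow(edges))
    stop("empty trainable network: no path from any target to any data site")

  ids <- unique(c(targets, edges$source, edges$target))
  kind <- ifelse(ids %in% targets, "target_kp",
          ifelse(isSiteId(ids),
                 ifelse(ids %in% perturbed, "data_site", "site"), "kp"))

  # prune to nodes reachable from the targets
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE, vertices = ids)
  dist <- igraph::distances(g, v = targets, mode = "out")
  dist <- if (length(targets) > 1L) apply(dist, 2, min) else drop(dist)
  reach <- names(dist)[is.finite(dist)]
  edges <- edges[edges$source %in% reach & edges$target %in% reach, ,
                 drop = FALSE]
  keep <- ids %in% reach
  nodes <- data.frame(id = ids[keep], kind = kind[keep],
                      distance = as.integer(dist[ids[keep]]),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  unreachable <- setdiff(perturbed, nodes$id[nodes$kind == "data_site"])
  if (!any(nodes$kind == "data_site"))
    stop("empty trainable network: no perturbed site reachable from targets")
  if (length(unreachable))
    message(length(unreachable), " perturbed site(s) unreachable from targets")

  new("BackgroundNetwork", nodes = nodes, edges = edges, targets = targets,
      limits = limits, unreachableSites = unreachable)
}

#' @describeIn buildBackground node table of a background network.
#' @param object a \code{BackgroundNetwork}.
#' @export
nodeTable <- function(object) {
  stopifnot(is(object, "BackgroundNetwork"))
  object@nodes
}

#' @describeIn buildBackground edge table of a background network.
#' @export
edgeTable <- function(object) {
  stopifnot(is(object, "BackgroundNetwork"))
  object@edges
}

#' @describeIn buildBackground the network as a directed igraph.
#' @export
backgroundGraph <- function(object) {
  stopifnot(is(object, "BackgroundNetwork"))
  igraph::graph_from_data_frame(
    object@edges[, c("source", "target", "kind")],
    directed = TRUE, vertices = object@nodes)
}

#' @export
setMethod("show", "BackgroundNetwork", function(object) {
  kinds <- table(object@nodes$kind)
  cat("BackgroundNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  cat("  ", paste(names(kinds), kinds, sep = ": ", collapse = ", "), "\n")
  cat("  targets:", paste(object@targets, collapse = ", "), "\n")
  if (length(object@unreachableSites))
    cat("  unreachable perturbed sites:",
        length(object@unreachableSites), "\n")
})
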