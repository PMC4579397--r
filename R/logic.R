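#' Sampling role of every background-network node
#'
#' Drug targets are roots (perturbed directly, no sampled inputs). Measured
#' data sites with no outgoing edges are sinks (exactly one upstream enzyme
#' in any model). Protein nodes, whose inputs are integrator edges from their
#' own sites, are integrators. Remaining site nodes are intermediates, whose
#' inputs combine under AND/OR gates.
#'
#' @param background a \linkS4class{BackgroundNetwork}.
#' @return named character vector: "root", "sink", "integrator" or
#'   "intermediate".
#' @export
nodeRoles <- function(background) {
  nodes <- nodeTable(background)
  edges <- edgeTable(background)
  indeg <- table(factor(edges$target, levels = nodes$id))
  outdeg <- table(factor(edges$source, levels = nodes$id))
  role <- ifelse(nodes$kind == "target_kp" | indeg[nodes$id] == 0L, "root",
          ifelse(nodes$kind == "kp", "integrator",
          ifelse(outdeg[nodes$id] == 0L, "sink", "intermediate")))
  stats::setNames(role, nodes$id)
}

#' Enumerate a node's allowed input combinations
#'
#' Returns every input combination a node of the given role can be assigned,
#' with its probability under the current sampling weights (the initial,
#' untrained weights by default).
#' \itemize{
#'   \item sink with m edges: the m single-edge inputs, probability 1/m each;
#'   \item integrator with m >= 2 edges: m singles, all edges under one AND,
#'     and no edge - probability 1/(m + 2) each (a one-edge integrator has
#'     just the single input and no edge, 1/2 each);
#'   \item intermediate: each edge is included independently with
#'     probability \code{pEdge}, and when two or more edges are included the
#'     gate is AND with probability \code{pAnd}, else OR. The induced
#'     outcome distribution over \{singles, no edge, AND, OR\} is returned
#'     (for two edges at the initial weights: 0.25, 0.25, 0.25, 0.125,
#'     0.125).
#' }
#'
#' @param sources character vector of input edge sources.
#' @param role "sink", "integrator" or "intermediate".
#' @param pEdge per-edge inclusion probabilities (intermediates; recycled).
#' @param pAnd AND-gate probability (intermediates).
#' @return data.frame with columns \code{sources} (";"-separated), \code{gate}
#'   (NONE, SINGLE, AND, OR), \code{size} and \code{prob}.
#' @export
enumerateCombinations <- function(sources, role = c("sink", "integrator",
                                                    "intermediate"),
                                  pEdge = 0.5, pAnd = 0.5) {
  role <- match.arg(role)
  m <- length(sources)
  if (m == 0L)
    return(data.frame(sources = character(), gate = character(),
                      size = integer(), prob = numeric()))
  if (role == "sink") {
    return(data.frame(sources = sources, gate = "SINGLE", size = 1L,
                      prob = rep(1 / m, m), stringsAsFactors = FALSE))
  }
  if (role == "integrator") {
    if (m == 1L)
      return(data.frame(sources = c(sources, ""), gate = c("SINGLE", "NONE"),
                        size = c(1L, 0L), prob = c(0.5, 0.5),
                        stringsAsFactors = FALSE))
    return(data.frame(
      sources = c(sources, paste(sources, collapse = ";"), ""),
      gate = c(rep("SINGLE", m), "AND", "NONE"),
      size = c(rep(1L, m), m, 0L),
      prob = rep(1 / (m + 2), m + 2), stringsAsFactors = FALSE))
  }
  # intermediate: enumerate subsets of included edges
  if (m > 12L) stop("refusing to enumerate > 2^12 input subsets")
  pEdge <- rep_len(pEdge, m)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  out <- do.call(rbind, lapply(seq_len(nrow(subsets)), function(i) {
    inc <- as.logical(subsets[i, ])
    p <- prod(ifelse(inc, pEdge, 1 - pEdge))
    k <- sum(inc)
    src <- paste(sources[inc], collapse = ";")
    if (k == 0L)
      data.frame(sources = "", gate = "NONE", size = 0L, prob = p,
                 stringsAsFactors = FALSE)
    else if (k == 1L)
      data.frame(sources = src, gate = "SINGLE", size = 1L, prob = p,
                 stringsAsFactors = FALSE)
    else
      data.frame(sources = src, gate = c("AND", "OR"), size = k,
                 prob = p * c(pAnd, 1 - pAnd), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Initial sampling weights over a background network
#'
#' Builds the per-node sampling state at its untrained starting point:
#' uniform categorical bins for sink and integrator nodes, and independent
#' per-edge inclusion probability \code{interInit} plus AND-gate probability
#' 0.5 for intermediates.
#'
#' @param background a \linkS4class{BackgroundNetwork}.
#' @param interInit initial per-edge inclusion probability for intermediate
#'   nodes: \code{"half"} (0.5 regardless of arity, default) or
#'   \code{"inverse"} (1/m).
#' @return a \linkS4class{SamplingWeights}.
#' @export
initialWeights <- function(background, interInit = c("half", "inverse")) {
  interInit <- match.arg(interInit)
  roles <- nodeRoles(background)
  edges <- edgeTable(background)
  nodes <- lapply(names(roles)[roles != "root"], function(v) {
    src <- edges$source[edges$target == v]
    role <- roles[[v]]
    spec <- list(node = v, role = role, sources = src)
    if (role %in% c("sink", "integrator")) {
      combos <- enumerateCombinations(src, role)
      spec$combos <- combos
      spec$counts <- rep(1, nrow(combos))
    } else {
      spec$pEdge <- rep(if (interInit == "half") 0.5 else 1 / length(src),
                        length(src))
      spec$pAnd <- 0.5
    }
    spec
  })
  names(nodes) <- names(roles)[roles != "root"]
  new("SamplingWeights", nodes = nodes)
}

#' @describeIn initialWeights current categorical probabilities / inclusion
#'   probabilities of one node.
#' @param object a \code{SamplingWeights}.
#' @param node node id.
#' @export
nodeWeights <- function(object, node) {
  stopifnot(is(object, "SamplingWeights"))
  spec <- object@nodes[[node]]
  if (is.null(spec)) stop("unknown or root node: ", node)
  if (spec$role %in% c("sink", "integrator")) {
    data.frame(sources = spec$combos$sources, gate = spec$combos$gate,
               prob = spec$counts / sum(spec$counts),
               stringsAsFactors = FALSE)
  } else {
    list(sources = spec$sources, pEdge = spec$pEdge, pAnd = spec$pAnd)
  }
}

#' @export
setMethod("show", "SamplingWeights", function(object) {
  roles <- vapply(object@nodes, `[[`, character(1), "role")
  cat("SamplingWeights over", length(object@nodes), "sampled nodes (",
      paste(names(table(roles)), table(roles), sep = ": ", collapse = ", "),
      ")\n")
})

# --- population sampling (internal) ---------------------------------------

# Draw n models at once; per categorical node an index vector, per
# intermediate node an inclusion matrix plus gate draws.
samplePopulation <- function(weights, n) {
  draws <- lapply(weights@nodes, function(spec) {
    if (spec$role %in% c("sink", "integrator")) {
      p <- spec$counts / sum(spec$counts)
      list(idx = sample.int(length(p), n, replace = TRUE, prob = p))
    } else {
      m <- length(spec$sources)
      incl <- matrix(stats::runif(n * m) < rep(spec$pEdge, each = n), n, m)
      list(incl = incl, gateAND = stats::runif(n) < spec$pAnd)
    }
  })
  structure(list(draws = draws, n = n), class = "logicPopulation")
}

popModel <- function(weights, pop, i) {
  asg <- lapply(weights@nodes, function(spec) {
    d <- pop$draws[[spec$node]]
    if (spec$role %in% c("sink", "integrator")) {
      cb <- spec$combos[d$idx[i], ]
      src <- if (nzchar(cb$sources))
        strsplit(cb$sources, ";", fixed = TRUE)[[1]] else character(0)
      list(sources = src, gate = cb$gate)
    } else {
      src <- spec$sources[d$incl[i, ]]
      gate <- if (length(src) == 0L) "NONE"
              else if (length(src) == 1L) "SINGLE"
              else if (d$gateAND[i]) "AND" else "OR"
      list(sources = src, gate = gate)
    }
  })
  asg
}

#' Sample one candidate logic model
#'
#' Draws an input combination for every sampled node independently under the
#' given weights.
#'
#' @param weights a \linkS4class{SamplingWeights}.
#' @param background the \linkS4class{BackgroundNetwork} the weights were
#'   built on (supplies the target/root nodes).
#' @return a \linkS4class{LogicModel}.
#' @export
sampleModel <- function(weights, background) {
  stopifnot(is(weights, "SamplingWeights"),
            is(background, "BackgroundNetwork"))
  pop <- samplePopulation(weights, 1L)
  new("LogicModel", assignments = popModel(weights, pop, 1L),
      targets = background@targets)
}

#' @export
setMethod("show", "LogicModel", function(object) {
  gates <- vapply(object@assignments, `[[`, character(1), "gate")
  cat("LogicModel:", length(object@assignments), "assigned nodes (",
      paste(names(table(gates)), table(gates), sep = ": ", collapse = ", "),
      ")\n")
  cat("  targets:", paste(object@targets, collapse = ", "), "\n")
})

#' Simulate a logic model to its fixpoint
#'
#' Perturbation states are propagated from the target nodes (state 1)
#' through the chosen input combinations until no node changes. States flip
#' only 0 -> 1, so every Boolean function involved is monotone and the
#' fixpoint is the unique least fixpoint; synchronous sweeps and random-order
#' asynchronous updates reach the same state, and the simulation terminates
#' within one sweep per node.
#'
#' @param model a \linkS4class{LogicModel}.
#' @param targets perturbed root nodes; defaults to the model's targets.
#' @param update \code{"synchronous"} (default) or \code{"asynchronous"}
#'   (random single-node updates; same fixpoint, used for testing).
#' @return named integer vector of node states (0 control / 1 perturbed).
#' @export
simulateModel <- function(model, targets = model@targets,
                          update = c("synchronous", "asynchronous")) {
  update <- match.arg(update)
  stopifnot(is(model, "LogicModel"))
  asg <- model@assignments
  ids <- unique(c(names(asg), targets,
                  unlist(lapply(asg, `[[`, "sources"), use.names = FALSE)))
  state <- stats::setNames(integer(length(ids)), ids)
  state[targets] <- 1L
  evalNode <- function(v) {
    a <- asg[[v]]
    if (a$gate == "NONE" || !length(a$sources)) return(0L)
    s <- state[a$sources]
    if (a$gate == "AND") as.integer(all(s == 1L)) else
      as.integer(any(s == 1L))
  }
  todo <- setdiff(names(asg), targets)  # targets keep their clamped state
  repeat {
    changed <- FALSE
    order_v <- if (update == "asynchronous") sample(todo) else todo
    if (update == "synchronous") {
      new <- state
      for (v in order_v) if (state[v] == 0L && evalNode(v) == 1L) {
        new[v] <- 1L; changed <- TRUE
      }
      state <- new
    } else {
      for (v in order_v) if (state[v] == 0L && evalNode(v) == 1L) {
        state[v] <- 1L; changed <- TRUE
      }
    }
    if (!changed) break
  }
  state
}

#' Predict perturbed sites per condition
#'
#' Simulates the model once per distinct target set of the drug panel
#' (conditions sharing targets share predictions) and reports, per
#' condition, the measured site nodes predicted perturbed.
#'
#' @param model a \linkS4class{LogicModel}.
#' @param panel named list: condition -> character vector of target ids.
#' @param sites site ids eligible for reporting (defaults to every site node
#'   appearing in the model).
#' @return named list: condition -> character vector of predicted perturbed
#'   site ids; conditions with no in-network target are flagged with a
#'   warning and return NULL.
#' @export
predictConditions <- function(model, panel, sites = NULL) {
  stopifnot(is(model, "LogicModel"), is.list(panel))
  known <- unique(c(names(model@assignments), model@targets))
  if (is.null(sites)) sites <- known[isSiteId(known)]
  usable <- vapply(panel, function(tg) any(tg %in% known), logical(1))
  if (any(!usable))
    warning("condition(s) with no in-network target excluded: ",
            paste(names(panel)[!usable], collapse = ", "))
  sig <- vapply(panel[usable], function(tg)
    paste(sort(intersect(tg, known)), collapse = "+"), character(1))
  preds <- stats::setNames(vector("list", length(panel)), names(panel))
  for (s in unique(sig)) {
    conds <- names(sig)[sig == s]
    st <- simulateModel(model, targets = intersect(panel[[conds[1]]], known))
    hit <- intersect(names(st)[st == 1L], sites)
    for (cc in conds) preds[[cc]] <- hit
  }
  preds
}

# --- vectorized population simulation (internal) ---------------------------

# Precompute per-node source indices and categorical combo masks against a
# fixed node ordering.
prepSimulation <- function(weights, background) {
  nodes <- nodeTable(background)
  ord <- order(nodes$distance, nodes$id)  # upstream first: fewer sweeps
  ids <- nodes$id[ord]
  idx <- stats::setNames(seq_along(ids), ids)
  specs <- lapply(weights@nodes, function(spec) {
    m <- length(spec$sources)
    out <- list(node = spec$node, role = spec$role,
                self = idx[[spec$node]], src = unname(idx[spec$sources]))
    if (spec$role %in% c("sink", "integrator")) {
      sel <- matrix(FALSE, nrow(spec$combos), m)
      for (r in seq_len(nrow(spec$combos))) {
        s <- spec$combos$sources[r]
        if (nzchar(s))
          sel[r, match(strsplit(s, ";", fixed = TRUE)[[1]],
                       spec$sources)] <- TRUE
      }
      out$comboSel <- sel
      out$comboAND <- spec$combos$gate == "AND"
      out$comboSize <- spec$combos$size
    }
    out
  })
  ordv <- order(vapply(specs, `[[`, numeric(1), "self"))
  list(ids = ids, idx = idx, specs = specs[ordv])
}

# Simulate every model in a population from one target set; returns an
# n x nodes logical state matrix.
simulatePopulation <- function(pop, prep, targets) {
  n <- pop$n
  state <- matrix(FALSE, n, length(prep$ids))
  ti <- prep$idx[intersect(targets, prep$ids)]
  state[, ti] <- TRUE
  clamped <- prep$ids[ti]
  repeat {
    changed <- FALSE
    for (sp in prep$specs) {
      if (sp$node %in% clamped) next
      cur <- state[, sp$self]
      if (all(cur)) next
      d <- pop$draws[[sp$node]]
      A <- state[, sp$src, drop = FALSE]
      if (!is.null(sp$comboSel)) {
        incl <- sp$comboSel[d$idx, , drop = FALSE]
        gAND <- sp$comboAND[d$idx]
      } else {
        incl <- d$incl
        gAND <- d$gateAND & rowSums(incl) >= 2L
      }
      nin <- rowSums(incl)
      act_or <- rowSums(A & incl) > 0L
      act_and <- rowSums(incl & !A) == 0L & nin > 0L
      act <- ifelse(gAND, act_and, act_or)
      new <- cur | act
      if (any(new != cur)) {
        state[, sp$self] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  colnames(state) <- prep$ids
  state
}

# Number of selected edges per model (size penalty term).
populationSizes <- function(pop, prep) {
  sz <- numeric(pop$n)
  for (sp in prep$specs) {
    d <- pop$draws[[sp$node]]
    sz <- sz + if (!is.null(sp$comboSize)) sp$comboSize[d$idx] else
      rowSums(d$incl)
  }
  sz
}
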