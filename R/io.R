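#' Read an intensity screen from TSV files
#'
#' The intensity table's first three columns are \code{peptide_id},
#' \code{protein} and \code{sites}; the remaining columns are samples. The
#' annotation table has columns \code{sample}, \code{condition},
#' \code{bio_rep}, \code{tech_rep}, \code{is_control}.
#'
#' @param intensityFile,annotationFile paths to the two TSVs.
#' @return a \linkS4class{PhosphoSet}.
#' @export
readIntensityTable <- function(intensityFile, annotationFile) {
  for (f in c(intensityFile, annotationFile))
    if (!file.exists(f)) stop("missing input file: ", f)
  tab <- utils::read.delim(intensityFile, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("peptide_id", "protein", "sites")
  if (!all(need %in% colnames(tab)[1:3]))
    stop(intensityFile, ": first columns must be ",
         paste(need, collapse = ", "))
  ann <- utils::read.delim(annotationFile, stringsAsFactors = FALSE)
  need_a <- c("sample", "condition", "bio_rep", "tech_rep", "is_control")
  if (!all(need_a %in% colnames(ann)))
    stop(annotationFile, ": needs columns ", paste(need_a, collapse = ", "))
  ann$is_control <- as.logical(ann$is_control)
  miss <- setdiff(ann$sample, colnames(tab))
  if (length(miss))
    stop(intensityFile, ": sample column(s) missing: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(tab[, ann$sample, drop = FALSE])
  mode(m) <- "numeric"
  PhosphoSet(m, tab[, need], ann)
}

#' @describeIn readIntensityTable write a PhosphoSet back to the same pair
#'   of TSVs.
#' @param object a \code{PhosphoSet}.
#' @param intensityFile,annotationFile output paths.
#' @export
writeIntensityTable <- function(object, intensityFile, annotationFile) {
  stopifnot(is(object, "PhosphoSet"))
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  out <- cbind(rd[, c("peptide_id", "protein", "sites")],
               as.data.frame(SummarizedExperiment::assay(object,
                                                         "intensity")))
  utils::write.table(out, intensityFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  utils::write.table(
    cd[, c("sample", "condition", "bio_rep", "tech_rep", "is_control")],
    annotationFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(intensityFile, annotationFile))
}

#' Read a drug panel table
#'
#' TSV with columns \code{condition} and \code{targets}
#' (";"-separated UPIDs).
#'
#' @param file path.
#' @return named list: condition -> character vector of targets.
#' @export
readDrugPanel <- function(file) {
  if (!file.exists(file)) stop("missing input file: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("condition", "targets") %in% colnames(tab)))
    stop(file, ": needs columns condition, targets")
  stats::setNames(strsplit(tab$targets, ";", fixed = TRUE), tab$condition)
}

#' @describeIn readDrugPanel write a drug panel list.
#' @param panel named list: condition -> targets.
#' @export
writeDrugPanel <- function(panel, file) {
  tab <- data.frame(condition = names(panel),
                    targets = vapply(panel, paste, character(1),
                                     collapse = ";"))
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the per-peptide effect table
#'
#' @param effects an \linkS4class{EffectResult}.
#' @param file output TSV path.
#' @export
writeEffectTable <- function(effects, file) {
  tab <- effectTable(effects)
  tab <- tab[order(tab$peptide_id, tab$condition), ]
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the mixture-fit summary
#'
#' One row per peptide: component count, parameters, BIC, overlap and the
#' Boolean-compliance flag.
#'
#' @param fits list of \linkS4class{GmmFit}.
#' @param file output TSV path.
#' @export
writeGmmSummary <- function(fits, file) {
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    peptide = f@peptide, K = f@K,
    means = paste(signif(f@mean, 6), collapse = ";"),
    sds = paste(signif(f@sd, 6), collapse = ";"),
    weights = paste(signif(f@weight, 6), collapse = ";"),
    bic = f@bic, control_component = f@controlComponent,
    overlap = f@overlap, boolean_ok = f@booleanOk,
    stringsAsFactors = FALSE)))
  tab <- tab[order(tab$peptide), ]
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write / read the evidence score matrix
#'
#' Long-format TSV: peptide, condition, S, label; site-level rows carry the
#' summed site evidence.
#'
#' @param smatrix an \linkS4class{SMatrix}.
#' @param file output TSV path.
#' @export
writeSMatrix <- function(smatrix, file) {
  stopifnot(is(smatrix, "SMatrix"))
  S <- smatrix@S
  pep <- if (nrow(S) && ncol(S))
    data.frame(level = "peptide",
               id = rep(rownames(S), ncol(S)),
               condition = rep(colnames(S), each = nrow(S)),
               S = as.vector(S),
               label = as.vector(smatrix@label),
               stringsAsFactors = FALSE)
  else
    data.frame(level = character(), id = character(),
               condition = character(), S = numeric(),
               label = character(), stringsAsFactors = FALSE)
  ss <- smatrix@siteS
  site <- data.frame(level = "site",
                     id = rep(rownames(ss), ncol(ss)),
                     condition = rep(colnames(ss), each = nrow(ss)),
                     S = as.vector(ss),
                     label = ifelse(as.vector(smatrix@sitePerturbed),
                                    "perturbed", "other"),
                     stringsAsFactors = FALSE)
  tab <- rbind(pep[!is.na(pep$S), ], site)
  tab <- tab[order(tab$level, tab$id, tab$condition), ]
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @describeIn writeSMatrix read an evidence matrix back. Peptide-level rows
#'   are restored as available; the site-level matrices are reconstructed
#'   exactly.
#' @param cut classification threshold recorded with the matrix.
#' @export
readSMatrix <- function(file, cut = 0.5) {
  if (!file.exists(file)) stop("missing input file: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  mk <- function(sub, val) {
    ids <- sort(unique(sub$id)); conds <- sort(unique(sub$condition))
    m <- matrix(NA_real_, length(ids), length(conds),
                dimnames = list(ids, conds))
    m[cbind(match(sub$id, ids), match(sub$condition, conds))] <- val
    m
  }
  pep <- tab[tab$level == "peptide", ]
  site <- tab[tab$level == "site", ]
  S <- if (nrow(pep)) mk(pep, pep$S) else
    matrix(numeric(), 0, 0)
  label <- S; if (nrow(pep)) {
    mode(label) <- "character"
    label[] <- classifySij(as.vector(S), cut = cut)
  }
  siteS <- mk(site, site$S)
  siteS[is.na(siteS)] <- 0
  new("SMatrix", S = S, label = label, siteS = siteS,
      sitePerturbed = siteS < -cut,
      siteMap = data.frame(peptide_id = character(), site = character()),
      cut = cut)
}

#' Export a network as Cytoscape-ready flat files
#'
#' Writes \code{<prefix>.sif} ("source TAB relation TAB target", relations
#' \code{kps-experimental}, \code{kps-predicted}, \code{integrator}),
#' \code{<prefix>_nodes.tsv} (node attributes: kind, distance where
#' available) and \code{<prefix>_edges.tsv} (edge attributes keyed
#' "source (relation) target", including consensus frequencies).
#'
#' @param object a \linkS4class{BackgroundNetwork} or
#'   \linkS4class{ConsensusNetwork}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeSif <- function(object, prefix) {
  if (is(object, "BackgroundNetwork")) {
    edges <- edgeTable(object)
    nodes <- nodeTable(object)
    edges$frequency <- NA_real_
  } else if (is(object, "ConsensusNetwork")) {
    edges <- object@edges
    nodes <- object@nodes
    nodes$distance <- NA_integer_
  } else stop("unsupported object class: ", class(object))
  rel <- ifelse(edges$kind == "integrator", "integrator",
                paste0("kps-", ifelse(is.na(edges$evidence) |
                                        edges$evidence == "experimental",
                                      "experimental", "predicted")))
  if (is(object, "ConsensusNetwork"))
    rel <- ifelse(edges$kind == "integrator", "integrator", "kps-trained")
  sif <- data.frame(source = edges$source, relation = rel,
                    target = edges$target)
  sif <- sif[order(sif$source, sif$target), ]
  files <- paste0(prefix, c(".sif", "_nodes.tsv", "_edges.tsv"))
  utils::write.table(sif, files[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  utils::write.table(nodes, files[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ea <- data.frame(key = paste0(edges$source, " (", rel, ") ",
                                edges$target),
                   frequency = edges$frequency)
  ea <- ea[order(ea$key), , drop = FALSE]
  utils::write.table(ea, files[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}

#' @describeIn writeSif read a SIF file back as an edge table.
#' @param file path to a .sif file.
#' @export
readSif <- function(file) {
  if (!file.exists(file)) stop("missing input file: ", file)
  tab <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("source", "relation", "target"))
  tab$kind <- ifelse(tab$relation == "integrator", "integrator", "kps")
  tab
}

#' @describeIn writeSif read a background network back from its flat files.
#' @param prefix path prefix used with \code{writeSif}.
#' @export
readBackground <- function(prefix) {
  sif <- readSif(paste0(prefix, ".sif"))
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- data.frame(source = sif$source, target = sif$target,
                      kind = sif$kind,
                      evidence = ifelse(sif$kind == "integrator",
                                        "integrator",
                                        sub("^kps-", "", sif$relation)),
                      stringsAsFactors = FALSE)
  new("BackgroundNetwork", nodes = nodes, edges = edges,
      targets = nodes$id[nodes$kind == "target_kp"],
      limits = pathLimits(), unreachableSites = character(0))
}

#' Write / read trained input frequencies
#'
#' Long-format TSV with one row per (node, input combination) plus per-edge
#' and gate rows, sorted for reproducible diffs.
#'
#' @param freqs frequency list ([combineRuns()] output or a run's
#'   \code{freqs} slot).
#' @param file path.
#' @export
writeFrequencies <- function(freqs, file) {
  rows <- list()
  for (v in sort(names(freqs))) {
    fr <- freqs[[v]]
    if (!is.null(fr$combo) && length(fr$combo))
      rows[[paste0(v, ".c")]] <- data.frame(
        node = v, type = "combo", key = names(fr$combo),
        frequency = unname(fr$combo), stringsAsFactors = FALSE)
    rows[[paste0(v, ".e")]] <- data.frame(
      node = v, type = "edge", key = names(fr$edge),
      frequency = unname(fr$edge), stringsAsFactors = FALSE)
    rows[[paste0(v, ".g")]] <- data.frame(
      node = v, type = "gateAND", key = "AND",
      frequency = fr$gateAND, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$node, tab$type, tab$key), ]
  rownames(tab) <- NULL
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @describeIn writeFrequencies read frequencies back into list form.
#' @export
readFrequencies <- function(file) {
  if (!file.exists(file)) stop("missing input file: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  out <- list()
  for (v in unique(tab$node)) {
    tv <- tab[tab$node == v, ]
    e <- tv[tv$type == "edge", ]
    cb <- tv[tv$type == "combo", ]
    out[[v]] <- list(
      sources = e$key,
      combo = stats::setNames(cb$frequency, cb$key),
      edge = stats::setNames(e$frequency, e$key),
      gateAND = tv$frequency[tv$type == "gateAND"])
  }
  out
}

#' Write / read a logic model
#'
#' TSV with columns node, sources (";"-separated) and gate.
#'
#' @param model a \linkS4class{LogicModel}.
#' @param file path.
#' @export
writeLogicModel <- function(model, file) {
  stopifnot(is(model, "LogicModel"))
  tab <- data.frame(
    node = names(model@assignments),
    sources = vapply(model@assignments, function(a)
      paste(a$sources, collapse = ";"), character(1)),
    gate = vapply(model@assignments, `[[`, character(1), "gate"),
    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(node = model@targets, sources = "",
                               gate = "TARGET"))
  tab <- tab[order(tab$node), ]
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @describeIn writeLogicModel read a logic model back.
#' @export
readLogicModel <- function(file) {
  if (!file.exists(file)) stop("missing input file: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  tab$sources[is.na(tab$sources)] <- ""
  targets <- tab$node[tab$gate == "TARGET"]
  tab <- tab[tab$gate != "TARGET", ]
  asg <- lapply(seq_len(nrow(tab)), function(i) list(
    sources = if (nzchar(tab$sources[i]))
      strsplit(tab$sources[i], ";", fixed = TRUE)[[1]] else character(0),
    gate = tab$gate[i]))
  names(asg) <- tab$node
  new("LogicModel", assignments = asg, targets = targets)
}

#' Write the per-generation score trajectory
#'
#' @param result a \linkS4class{TrainingResult}.
#' @param file path.
#' @export
writeTrajectory <- function(result, file) {
  stopifnot(is(result, "TrainingResult"))
  utils::write.table(result@trajectory, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @describeIn loadKps write a K/P-S edge table.
#' @param kps edge table.
#' @param file path.
#' @export
writeKps <- function(kps, file) {
  utils::write.table(
    kps[, c("enzyme", "substrate", "residue", "position", "evidence",
            "motif_score", "context_score", "source")],
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
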