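#' Load and filter a kinase/phosphatase-substrate table
#'
#' Reads a K/P-S interaction table (merged from resources such as
#' Phospho.ELM, PhosphoSitePlus, HPRD, NetworKIN, DEPOD, pre-mapped to a
#' simple TSV schema), applies the prediction-score filter and an enzyme
#' blocklist, and collapses duplicates keeping the strongest evidence class.
#'
#' Predicted interactions with either motif or context score below
#' \code{minScore} are excluded. Rows with an unknown residue code or a
#' non-positive position are rejected; a warning reports how many rows were
#' skipped.
#'
#' @param x path to a TSV file or a data.frame with columns \code{enzyme},
#'   \code{substrate}, \code{residue}, \code{position}, \code{evidence}
#'   ("experimental" or "predicted"); optional \code{motif_score},
#'   \code{context_score}, \code{source}.
#' @param minScore score threshold for predicted interactions (default 0.5).
#' @param blocklist enzymes whose predicted interactions are dropped
#'   (e.g. promiscuous kinase predictions).
#' @return data.frame of edges with an added \code{site} column
#'   ("UPID.RESPOS").
#' @export
loadKps <- function(x, minScore = 0.5, blocklist = character()) {
  kps <- if (is.character(x))
    utils::read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  need <- c("enzyme", "substrate", "residue", "position", "evidence")
  if (!all(need %in% colnames(kps)))
    stop("K/P-S table must contain columns: ", paste(need, collapse = ", "))
  for (cc in c("motif_score", "context_score"))
    if (!cc %in% colnames(kps)) kps[[cc]] <- NA_real_
  if (!"source" %in% colnames(kps)) kps$source <- NA_character_
  if (!nrow(kps)) { kps$site <- character(0); return(kps) }

  kps$position <- suppressWarnings(as.integer(kps$position))
  bad <- !(kps$residue %in% c("S", "T", "Y")) |
    is.na(kps$position) | kps$position < 1L |
    !(kps$evidence %in% c("experimental", "predicted")) |
    is.na(kps$enzyme) | is.na(kps$substrate)
  if (any(bad)) {
    warning(sum(bad), " malformed K/P-S rows skipped")
    kps <- kps[!bad, , drop = FALSE]
  }

  pred <- kps$evidence == "predicted"
  low <- pred & (is.na(kps$motif_score) | kps$motif_score < minScore |
                 is.na(kps$context_score) | kps$context_score < minScore)
  blocked <- pred & kps$enzyme %in% blocklist
  kps <- kps[!(low | blocked), , drop = FALSE]

  # collapse duplicates, experimental evidence wins
  kps <- kps[order(kps$evidence != "experimental"), , drop = FALSE]
  key <- paste(kps$enzyme, kps$substrate, kps$residue, kps$position)
  kps <- kps[!duplicated(key), , drop = FALSE]
  kps$site <- paste0(kps$substrate, ".", kps$residue, kps$position)
  rownames(kps) <- NULL
  kps
}

#' Project site-level interactions to the protein level
#'
#' A directed protein edge K1 -> K2 exists iff K1 has a K/P-S edge onto any
#' site of protein K2.
#'
#' @param kps a K/P-S edge table (see [loadKps()]).
#' @return directed \link[igraph]{igraph} graph over proteins.
#' @export
proteinProjection <- function(kps) {
  stopifnot(nrow(kps) >= 1L)
  pe <- unique(kps[, c("enzyme", "substrate")])
  igraph::graph_from_data_frame(pe, directed = TRUE)
}

#' Shuffle the enzyme side of a K/P-S network
#'
#' Control used to test whether network structure is informative: the enzyme
#' column is permuted uniformly at random while the substrate/site column,
#' and hence the edge count and the substrate-side degree distribution, are
#' untouched.
#'
#' @param kps a K/P-S edge table.
#' @return the table with permuted \code{enzyme} assignments.
#' @export
randomizeKps <- function(kps) {
  stopifnot(nrow(kps) >= 2L)
  kps$enzyme <- sample(kps$enzyme)
  kps
}
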