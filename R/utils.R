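#' Build site identifiers from protein and site annotations
#'
#' Site ids follow the "UPID.RESPOS" convention, e.g. \code{"AKT1.S473"}.
#' A multiply phosphorylated peptide (sites \code{"S473;T308"}) maps to one
#' id per site.
#'
#' @param protein character vector of host protein UPIDs.
#' @param sites character vector of same length; each entry one or more
#'   residue/position tokens separated by ";".
#' @return list (one element per input) of character vectors of site ids.
#' @export
#' @examples
#' siteIds("AKT1", "S473")
#' siteIds("RPS6", "S235;S236")
siteIds <- function(protein, sites) {
  stopifnot(length(protein) == length(sites))
  toks <- strsplit(as.character(sites), ";", fixed = TRUE)
  mapply(function(p, tk) {
    tk <- trimws(tk)
    tk <- tk[nzchar(tk)]
    if (!length(tk)) return(character(0))
    bad <- !grepl("^[STY][0-9]+$", tk)
    if (any(bad))
      stop("malformed site token(s): ", paste(tk[bad], collapse = ", "))
    paste0(p, ".", tk)
  }, protein, toks, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# host protein of a site id ("AKT1.S473" -> "AKT1")
siteHost <- function(site) sub("\\.[STY][0-9]+$", "", site)

# is this id a site id (as opposed to a bare protein id)?
isSiteId <- function(id) grepl("\\.[STY][0-9]+$", id)

# Derive per-run sub-seeds from a master seed, independent of execution order.
# Kept below 2^31 so they are valid R integer seeds.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# canonical key of an input combination, used for frequency bookkeeping
comboKey <- function(sources, gate) {
  if (gate == "NONE" || !length(sources)) return("NONE")
  paste0(gate, ":", paste(sort(sources), collapse = "+"))
}
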