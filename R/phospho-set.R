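#' Construct a PhosphoSet
#'
#' Bundles a phosphopeptide intensity matrix with its peptide and sample
#' annotation. Intensities are raw (linear-scale) peak heights; zeros and
#' missing values are allowed and are masked during normalization.
#'
#' @param intensity numeric matrix, peptides x samples.
#' @param peptides data.frame with columns \code{peptide_id}, \code{protein}
#'   (UPID) and \code{sites} (e.g. \code{"S473"} or \code{"S473;T308"}).
#' @param samples data.frame with columns \code{sample}, \code{condition},
#'   \code{bio_rep}, \code{tech_rep}, \code{is_control}; rows must match the
#'   columns of \code{intensity}.
#' @return a \linkS4class{PhosphoSet}.
#' @export
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' pep <- data.frame(peptide_id = paste0("p", 1:3),
#'                   protein = c("AKT1", "GSK3B", "RPS6"),
#'                   sites = c("S473", "S9", "S235;S236"))
#' ann <- data.frame(sample = paste0("s", 1:4),
#'                   condition = c("CTRL", "CTRL", "DRUG", "DRUG"),
#'                   bio_rep = c(1, 2, 1, 2), tech_rep = 1,
#'                   is_control = c(TRUE, TRUE, FALSE, FALSE))
#' ps <- PhosphoSet(m, pep, ann)
PhosphoSet <- function(intensity, peptides, samples) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity))) colnames(intensity) <- samples$sample
  stopifnot(nrow(intensity) == nrow(peptides),
            ncol(intensity) == nrow(samples))
  if (!identical(colnames(intensity), as.character(samples$sample)))
    intensity <- intensity[, as.character(samples$sample), drop = FALSE]
  rownames(intensity) <- peptides$peptide_id
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample)
  rd <- S4Vectors::DataFrame(peptides, row.names = peptides$peptide_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), rowData = rd, colData = cd)
  new("PhosphoSet", se)
}

#' @describeIn PhosphoSet name of the control condition.
#' @param object,x a \code{PhosphoSet}.
#' @export
controlCondition <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  as.character(unique(cd$condition[as.logical(cd$is_control)]))
}

#' @export
setMethod("show", "PhosphoSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PhosphoSet:", nrow(object), "peptide ions x", ncol(object), "samples\n")
  cat("  conditions:", length(unique(cd$condition)),
      "(control:", controlCondition(object), ")\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

#' Log-transform and quantile-normalize intensities
#'
#' Masks non-positive or missing intensities, takes log2, and quantile
#' normalizes sample columns over the non-missing entries so that every
#' sample shares the same intensity distribution. With a single sample only
#' the log transform is applied. The result is stored as a new assay
#' \code{"lognorm"}.
#'
#' @param object a \linkS4class{PhosphoSet}.
#' @return the \code{PhosphoSet} with an added \code{"lognorm"} assay;
#'   peptides with no usable value in any sample are retained but flagged in
#'   \code{rowData()$all_missing}.
#' @export
normalizeIntensities <- function(object) {
  stopifnot(is(object, "PhosphoSet"), ncol(object) >= 1L)
  a <- SummarizedExperiment::assay(object, "intensity")
  n_masked <- sum(a <= 0, na.rm = TRUE)
  a[a <= 0] <- NA
  if (n_masked > 0)
    message(n_masked, " non-positive intensities masked as missing")
  lg <- log2(a)
  norm <- if (ncol(lg) > 1L) limma::normalizeQuantiles(lg) else lg
  dimnames(norm) <- dimnames(lg)
  SummarizedExperiment::assay(object, "lognorm") <- norm
  all_missing <- rowSums(!is.na(norm)) == 0L
  SummarizedExperiment::rowData(object)$all_missing <- all_missing
  if (any(all_missing))
    message(sum(all_missing), " peptides have no usable intensity in any sample")
  object
}
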