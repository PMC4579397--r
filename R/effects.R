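#' Estimate per-condition perturbation effects
#'
#' Fits, across all peptides, a linear model of normalized log2 intensity on
#' condition plus biological replicate, and contrasts every drug condition
#' against the control. Technical replicates are averaged within
#' (condition, biological replicate) before fitting, so they enter as
#' exchangeable observations. Standard errors are moderated by empirical
#' Bayes shrinkage across peptides
#' (\eqn{s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)}, with the prior
#' \eqn{(d_0, s_0^2)} estimated by moment matching on the log residual
#' variances), and p-values are Benjamini-Hochberg adjusted within each
#' condition. The machinery is limma's.
#'
#' A peptide/condition pair keeps its estimate only when at least
#' \code{minObs} raw intensity observations support it; peptides whose
#' control intensity cannot be estimated are excluded entirely (all effects
#' NA). The control condition is carried as a zero-effect column.
#'
#' @param object a \linkS4class{PhosphoSet} with a \code{"lognorm"} assay
#'   (see [normalizeIntensities()]).
#' @param minObs minimum raw observations per (peptide, condition); default 2.
#' @return an \linkS4class{EffectResult}.
#' @export
fitEffects <- function(object, minObs = 2L) {
  stopifnot(is(object, "PhosphoSet"))
  if (!"lognorm" %in% SummarizedExperiment::assayNames(object))
    object <- normalizeIntensities(object)
  y <- SummarizedExperiment::assay(object, "lognorm")
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  ctl <- controlCondition(object)
  cond <- factor(cd$condition)
  conds <- levels(cond)
  drugs <- setdiff(conds, ctl)

  # pool technical replicates: mean within (condition, bio replicate)
  unit <- interaction(cd$condition, cd$bio_rep, drop = TRUE, sep = "||")
  units <- levels(unit)
  avg <- vapply(units, function(u)
    rowMeans(y[, unit == u, drop = FALSE], na.rm = TRUE), numeric(nrow(y)))
  avg[is.nan(avg)] <- NA
  ucond <- factor(sub("\\|\\|.*$", "", units), levels = conds)
  ubio <- factor(sub("^.*\\|\\|", "", units))

  design <- if (nlevels(ubio) > 1L)
    stats::model.matrix(~ 0 + ucond + ubio) else
    stats::model.matrix(~ 0 + ucond)
  colnames(design) <- sub("^ucond", "", colnames(design))

  fit <- limma::lmFit(avg, design)
  cm <- vapply(drugs, function(d) {
    v <- numeric(ncol(design)); names(v) <- colnames(design)
    v[d] <- 1; v[ctl] <- -1; v
  }, numeric(ncol(design)))
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))

  logFC <- fit2$coefficients
  se <- sqrt(fit2$s2.post) * fit2$stdev.unscaled
  tmat <- fit2$t
  pmat <- fit2$p.value

  # observation counts from the raw (un-pooled) data
  nobs <- vapply(conds, function(cc)
    rowSums(!is.na(y[, cd$condition == cc, drop = FALSE])),
    numeric(nrow(y)))
  no_control <- nobs[, ctl] < minObs
  for (d in drugs) {
    drop <- nobs[, d] < minObs | no_control
    logFC[drop, d] <- se[drop, d] <- tmat[drop, d] <- pmat[drop, d] <- NA
  }
  if (any(no_control))
    message(sum(no_control),
            " peptides excluded: control intensity not estimable")

  padj <- pmat
  for (d in drugs) padj[, d] <- stats::p.adjust(pmat[, d], method = "BH")

  # control column: zero effect by construction (NA when not estimable)
  add0 <- function(m, fill0, fill1 = fill0) {
    m <- cbind(m, ifelse(no_control, NA, fill0))
    colnames(m)[ncol(m)] <- ctl
    m[, conds, drop = FALSE]
  }
  logFC <- add0(logFC, 0); se <- add0(se, 0); tmat <- add0(tmat, 0)
  pmat <- add0(pmat, 1); padj <- add0(padj, 1)

  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  new("EffectResult", logFC = logFC, se = se, t = tmat, pvalue = pmat,
      padj = padj, nobs = nobs[, conds, drop = FALSE], control = ctl,
      peptides = rd[, c("peptide_id", "protein", "sites")],
      prior = list(df = fit2$df.prior, s2 = fit2$s2.prior,
                   df.residual = fit2$df.residual,
                   sigma2 = fit2$sigma^2))
}

#' @describeIn fitEffects the peptide x condition log2 fold-change matrix
#'   (control column zero).
#' @export
effectsMatrix <- function(object) {
  stopifnot(is(object, "EffectResult"))
  object@logFC
}

#' @export
setMethod("show", "EffectResult", function(object) {
  cat("EffectResult:", nrow(object@logFC), "peptides x",
      ncol(object@logFC), "conditions (control:", object@control, ")\n")
  cat("  estimable peptides:", sum(stats::complete.cases(object@logFC)), "\n")
})

#' Tidy per-peptide, per-condition effect table
#'
#' @param object an \linkS4class{EffectResult}.
#' @return data.frame in long format: peptide_id, condition, logFC, se, t,
#'   pvalue, padj, n_obs.
#' @export
effectTable <- function(object) {
  stopifnot(is(object, "EffectResult"))
  conds <- colnames(object@logFC)
  peps <- rownames(object@logFC)
  data.frame(
    peptide_id = rep(peps, times = length(conds)),
    condition = rep(conds, each = length(peps)),
    logFC = as.vector(object@logFC), se = as.vector(object@se),
    t = as.vector(object@t), pvalue = as.vector(object@pvalue),
    padj = as.vector(object@padj), n_obs = as.vector(object@nobs),
    stringsAsFactors = FALSE)
}
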