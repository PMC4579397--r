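#' Fit a Gaussian mixture to one peptide's effect profile
#'
#' Fits univariate Gaussian mixtures with 1 to \code{maxK} components (equal-
#' and unequal-variance parameterizations, via mclust) to the vector of
#' per-condition effect estimates of a single peptide and keeps the
#' BIC-optimal model. Component variances are floored at \code{varFloor} and
#' the reported log-likelihood and BIC (\eqn{-2\log L + p \ln n}, smaller is
#' better) are recomputed at the final parameters.
#'
#' The component with maximal posterior responsibility at
#' \code{controlValue} (the control condition's effect, zero by construction)
#' is the control population; for two-component fits the other component is
#' the perturbed population. A fit is Boolean-compliant (\code{booleanOk})
#' only when K = 2, the control component is defined, and the two component
#' densities overlap by at most \code{overlapMax} (see [overlapFraction()]).
#'
#' @param x numeric vector of effect values (one per condition), NAs dropped.
#' @param peptide peptide identifier stored in the result.
#' @param controlValue effect value of the control condition (default 0).
#' @param maxK maximum number of components (default 9).
#' @param varFloor variance floor in squared log2-FC units (default 1e-4).
#' @param overlapMax maximal tolerated overlap fraction (default 0.10).
#' @param convention overlap convention passed to [overlapFraction()].
#' @return a \linkS4class{GmmFit}.
#' @importFrom mclust Mclust mclustBIC
#' @export
fitPeptideGmm <- function(x, peptide = "peptide", controlValue = 0,
                          maxK = 9L, varFloor = 1e-4, overlapMax = 0.10,
                          convention = c("mass", "area")) {
  convention <- match.arg(convention)
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 3L)

  mk <- function(K, mean, sd, weight, modelName) {
    sd <- pmax(sd, sqrt(varFloor))
    ll <- .gmmLoglik(x, mean, sd, weight)
    p <- if (modelName == "E") 2L * K else 3L * K - 1L
    list(K = K, mean = mean, sd = sd, weight = weight, loglik = ll,
         bic = -2 * ll + p * log(n), p = p)
  }

  fitted <- NULL
  if (stats::sd(x) > sqrt(varFloor) / 10) {
    mc <- try(suppressWarnings(
      Mclust(x, G = seq_len(min(maxK, max(2L, n %/% 2L))),
                     modelNames = c("E", "V"), verbose = FALSE)),
      silent = TRUE)
    if (!inherits(mc, "try-error") && !is.null(mc) && !is.null(mc$parameters)) {
      K <- mc$G
      sig2 <- mc$parameters$variance$sigmasq
      if (length(sig2) == 1L) sig2 <- rep(sig2, K)
      fitted <- mk(K, as.numeric(mc$parameters$mean), sqrt(sig2),
                   if (K == 1L) 1 else mc$parameters$pro, mc$modelName)
    }
  }
  if (is.null(fitted)) # degenerate or non-convergent profile: one component
    fitted <- mk(1L, mean(x), stats::sd(x), 1, "V")

  post <- .gmmResponsibilities(controlValue, fitted$mean, fitted$sd,
                               fitted$weight)
  ctrl <- if (all(is.finite(post))) which.max(post) else NA_integer_
  pert <- if (!is.na(ctrl) && fitted$K == 2L) 3L - ctrl else NA_integer_

  fit <- new("GmmFit", peptide = peptide, K = as.integer(fitted$K),
             mean = fitted$mean, sd = fitted$sd, weight = fitted$weight,
             loglik = fitted$loglik, bic = fitted$bic,
             nParams = as.integer(fitted$p), n = as.integer(n),
             controlComponent = as.integer(ctrl),
             perturbedComponent = as.integer(pert),
             overlap = NA_real_, booleanOk = FALSE)
  if (fit@K == 2L && !is.na(ctrl)) {
    fit@overlap <- overlapFraction(fit, convention = convention)
    fit@booleanOk <- fit@overlap <= overlapMax
  }
  fit
}

.gmmLoglik <- function(x, mean, sd, weight) {
  dens <- vapply(seq_along(mean), function(k)
    weight[k] * stats::dnorm(x, mean[k], sd[k]), numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

.gmmResponsibilities <- function(x, mean, sd, weight) {
  d <- weight * stats::dnorm(x, mean, sd)
  d / sum(d)
}

#' Overlap between the two component densities of a mixture fit
#'
#' Computes \eqn{\int \min(\pi_1 f_1, \pi_2 f_2) dx} by adaptive quadrature
#' over the union of both components' \eqn{\mu \pm 8\sigma} ranges. Under the
#' default \code{"mass"} convention the integral is normalized by
#' \eqn{\min(\pi_1, \pi_2)}, so two identical components overlap by exactly 1
#' regardless of their weights; \code{"area"} returns the raw integral.
#' Fits with an overlap above 10\% are not considered Boolean-compliant.
#'
#' @param fit a \linkS4class{GmmFit} with K = 2.
#' @param convention \code{"mass"} (default) or \code{"area"}.
#' @return overlap fraction in [0, 1].
#' @export
overlapFraction <- function(fit, convention = c("mass", "area")) {
  convention <- match.arg(convention)
  stopifnot(is(fit, "GmmFit"))
  if (fit@K != 2L) stop("overlapFraction requires a two-component fit")
  lo <- min(fit@mean - 8 * fit@sd)
  hi <- max(fit@mean + 8 * fit@sd)
  f <- function(x)
    pmin(fit@weight[1] * stats::dnorm(x, fit@mean[1], fit@sd[1]),
         fit@weight[2] * stats::dnorm(x, fit@mean[2], fit@sd[2]))
  area <- stats::integrate(f, lo, hi, rel.tol = 1e-9,
                           subdivisions = 500L)$value
  if (convention == "mass") area <- area / min(fit@weight)
  min(max(area, 0), 1)
}

#' Evidence score of one measurement under a mixture fit
#'
#' \eqn{S = \log_{10}(P(C)/P(P))}: the log ratio of the probability that the
#' measurement belongs to the control versus the perturbed component.
#' Negative values indicate the measurement is more likely perturbed. By
#' default the probabilities are posterior responsibilities (component
#' weights included); \code{useWeights = FALSE} uses the raw densities.
#' Scores are clamped to \code{[-clamp, clamp]} against numerical underflow.
#'
#' @param fit a Boolean-compliant \linkS4class{GmmFit}.
#' @param x numeric vector of effect values.
#' @param useWeights include mixture weights (default TRUE).
#' @param clamp score magnitude ceiling (default 10).
#' @return numeric vector of S scores.
#' @export
computeSij <- function(fit, x, useWeights = TRUE, clamp = 10) {
  stopifnot(is(fit, "GmmFit"))
  if (fit@K != 2L || is.na(fit@controlComponent))
    stop("computeSij requires a two-component fit with a control component")
  ci <- fit@controlComponent; pi_ <- fit@perturbedComponent
  lc <- stats::dnorm(x, fit@mean[ci], fit@sd[ci], log = TRUE)
  lp <- stats::dnorm(x, fit@mean[pi_], fit@sd[pi_], log = TRUE)
  if (useWeights) {
    lc <- lc + log(fit@weight[ci])
    lp <- lp + log(fit@weight[pi_])
  }
  s <- (lc - lp) / log(10)
  pmin(pmax(s, -clamp), clamp)
}

#' Classify an evidence score
#'
#' A measurement is called perturbed when S < -cut, in the control state when
#' S > cut, and undetermined inside the dead zone.
#'
#' @param S numeric vector of scores.
#' @param cut threshold (default 0.5).
#' @return character vector: "perturbed", "control" or "undetermined" (NA in,
#'   NA out).
#' @export
classifySij <- function(S, cut = 0.5) {
  out <- rep(NA_character_, length(S))
  out[!is.na(S) & S < -cut] <- "perturbed"
  out[!is.na(S) & S > cut] <- "control"
  out[!is.na(S) & abs(S) <= cut] <- "undetermined"
  out
}

#' @export
setMethod("show", "GmmFit", function(object) {
  cat("GmmFit", object@peptide, ": K =", object@K,
      "| BIC =", round(object@bic, 2),
      "| booleanOk =", object@booleanOk, "\n")
  if (object@K == 2L)
    cat("  means:", paste(round(object@mean, 3), collapse = ", "),
        "| overlap =", signif(object@overlap, 3),
        "| control component =", object@controlComponent, "\n")
})

#' Booleanize a full effect matrix
#'
#' Runs [fitPeptideGmm()] on every peptide of an effect result, computes
#' S scores for Boolean-compliant (two-population, well-separated) peptides
#' across all conditions, labels each (peptide, condition), and aggregates
#' scores to the site level: peptides mapping to the same phosphosite
#' contribute their S as independent pieces of evidence (summed). A site is
#' called perturbed under a condition when its summed score is below
#' \code{-cut}.
#'
#' @param effects an \linkS4class{EffectResult}.
#' @param maxK,varFloor,overlapMax,convention passed to [fitPeptideGmm()].
#' @param seFloor if TRUE (default), each peptide's component sds are
#'   additionally floored at the median moderated standard error of its
#'   effect estimates: a fitted population narrower than the measurement
#'   noise is an artifact, and flooring lets the overlap filter remove such
#'   splits instead of mistaking them for well-separated states.
#' @param useWeights,clamp passed to [computeSij()].
#' @param cut classification threshold (default 0.5).
#' @return list with elements \code{fits} (list of \linkS4class{GmmFit}) and
#'   \code{smatrix} (an \linkS4class{SMatrix}).
#' @export
booleanizeEffects <- function(effects, maxK = 9L, varFloor = 1e-4,
                              overlapMax = 0.10,
                              convention = c("mass", "area"),
                              seFloor = TRUE, useWeights = TRUE, clamp = 10,
                              cut = 0.5) {
  stopifnot(is(effects, "EffectResult"))
  convention <- match.arg(convention)
  lf <- effects@logFC
  fits <- vector("list", nrow(lf))
  names(fits) <- rownames(lf)
  for (i in seq_len(nrow(lf))) {
    xi <- lf[i, ]
    if (sum(is.finite(xi)) < 3L) next
    floor_i <- varFloor
    if (seFloor) {
      sei <- effects@se[i, ]
      sei <- sei[is.finite(sei) & sei > 0]
      if (length(sei)) floor_i <- max(varFloor, stats::median(sei)^2)
    }
    fits[[i]] <- fitPeptideGmm(xi, peptide = rownames(lf)[i],
                               controlValue = 0, maxK = maxK,
                               varFloor = floor_i, overlapMax = overlapMax,
                               convention = convention)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  sm <- scoreMatrix(effects, fits, useWeights = useWeights, clamp = clamp,
                    cut = cut)
  list(fits = fits, smatrix = sm)
}

#' Assemble the S evidence matrix
#'
#' @param effects an \linkS4class{EffectResult}.
#' @param fits list of \linkS4class{GmmFit}, named by peptide.
#' @param useWeights,clamp passed to [computeSij()].
#' @param cut classification threshold.
#' @return an \linkS4class{SMatrix}.
#' @export
scoreMatrix <- function(effects, fits, useWeights = TRUE, clamp = 10,
                        cut = 0.5) {
  stopifnot(is(effects, "EffectResult"))
  lf <- effects@logFC
  S <- matrix(NA_real_, nrow(lf), ncol(lf), dimnames = dimnames(lf))
  for (f in fits) {
    if (!f@booleanOk) next
    i <- f@peptide
    xi <- lf[i, ]
    ok <- is.finite(xi)
    S[i, ok] <- computeSij(f, xi[ok], useWeights = useWeights, clamp = clamp)
  }
  label <- S
  mode(label) <- "character"
  label[] <- classifySij(as.vector(S), cut = cut)

  # site-level aggregation
  pep <- effects@peptides
  ids <- siteIds(pep$protein, pep$sites)
  map <- data.frame(
    peptide_id = rep(pep$peptide_id, lengths(ids)),
    site = unlist(ids, use.names = FALSE), stringsAsFactors = FALSE)
  scored <- rownames(S)[rowSums(!is.na(S)) > 0L]
  map_s <- map[map$peptide_id %in% scored, , drop = FALSE]
  sites <- sort(unique(map_s$site))
  siteS <- matrix(0, length(sites), ncol(S),
                  dimnames = list(sites, colnames(S)))
  for (r in seq_len(nrow(map_s))) {
    v <- S[map_s$peptide_id[r], ]
    v[is.na(v)] <- 0
    siteS[map_s$site[r], ] <- siteS[map_s$site[r], ] + v
  }
  new("SMatrix", S = S, label = label, siteS = siteS,
      sitePerturbed = siteS < -cut, siteMap = map, cut = cut)
}

#' @describeIn scoreMatrix sites called perturbed in at least one of the
#'   given conditions (all conditions by default).
#' @param object an \code{SMatrix}.
#' @param conditions conditions to consider.
#' @export
perturbedSites <- function(object, conditions = colnames(object@siteS)) {
  stopifnot(is(object, "SMatrix"))
  m <- object@sitePerturbed[, conditions, drop = FALSE]
  rownames(m)[rowSums(m) > 0L]
}

#' @describeIn scoreMatrix site x condition summed score matrix.
#' @export
siteScores <- function(object) {
  stopifnot(is(object, "SMatrix"))
  object@siteS
}

#' @export
setMethod("show", "SMatrix", function(object) {
  nb <- sum(rowSums(!is.na(object@S)) > 0L)
  cat("SMatrix:", nrow(object@S), "peptides x", ncol(object@S),
      "conditions;", nb, "Boolean-compliant peptides\n")
  cat("  sites:", nrow(object@siteS), "| perturbed in >=1 condition:",
      length(perturbedSites(object)), "\n")
})
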