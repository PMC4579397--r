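test_that("quantile normalization is identity on identical columns and log2 on one sample", {
  m <- matrix(2^c(1, 3, 5), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  pep <- data.frame(peptide_id = paste0("p", 1:3), protein = "A",
                    sites = paste0("S", 1:3))
  ann <- data.frame(sample = c("s1", "s2"), condition = c("CTRL", "D"),
                    bio_rep = 1, tech_rep = 1,
                    is_control = c(TRUE, FALSE))
  ps <- normalizeIntensities(PhosphoSet(m, pep, ann))
  expect_equal(unname(SummarizedExperiment::assay(ps, "lognorm")),
               unname(log2(m)))

  ps1 <- normalizeIntensities(PhosphoSet(m[, 1, drop = FALSE], pep,
                                         ann[1, ]))
  lg <- SummarizedExperiment::assay(ps1, "lognorm")
  expect_equal(unname(lg[, 1]), c(1, 3, 5))
})

test_that("quantile normalization matches the rank/row-mean oracle and equalizes distributions", {
  set.seed(11)
  m <- matrix(2^runif(12, 10, 20), 4, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  pep <- data.frame(peptide_id = paste0("p", 1:4), protein = "A",
                    sites = paste0("S", 1:4))
  ann <- data.frame(sample = paste0("s", 1:3),
                    condition = c("CTRL", "D", "D"),
                    bio_rep = c(1, 1, 2), tech_rep = 1,
                    is_control = c(TRUE, FALSE, FALSE))
  ps <- normalizeIntensities(PhosphoSet(m, pep, ann))
  lg <- SummarizedExperiment::assay(ps, "lognorm")
  expect_equal(unname(lg), unname(qnOracle(log2(m))), tolerance = 1e-12)
  sorted <- apply(lg, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # non-positive intensities are masked, all-missing peptides flagged
  m2 <- m; m2[2, ] <- 0
  suppressMessages(ps2 <- normalizeIntensities(PhosphoSet(m2, pep, ann)))
  expect_true(all(is.na(SummarizedExperiment::assay(ps2, "lognorm")[2, ])))
  expect_true(SummarizedExperiment::rowData(ps2)$all_missing[2])
})

test_that("effects are zero for conditions identical to control and peptides lacking control are excluded", {
  # peptide 1 is constant everywhere (logFC 0, t 0); the rest carry noise
  # so the variance prior is well defined
  set.seed(2)
  conds <- c("CTRL", "D1")
  samples <- expand.grid(bio_rep = 1:3, condition = conds,
                         stringsAsFactors = FALSE)
  samples$sample <- paste(samples$condition, samples$bio_rep, sep = "_")
  samples$tech_rep <- 1
  samples$is_control <- samples$condition == "CTRL"
  m <- 2^matrix(rnorm(5 * nrow(samples), 20, 0.5), 5)
  m[1, ] <- 2^20
  colnames(m) <- samples$sample
  pep <- data.frame(peptide_id = paste0("p", 1:5), protein = "A",
                    sites = paste0("S", 1:5))
  ps <- PhosphoSet(m, pep, samples[, c("sample", "condition", "bio_rep",
                                       "tech_rep", "is_control")])
  # fit on the log values as-is (normalization semantics tested elsewhere)
  SummarizedExperiment::assay(ps, "lognorm", withDimnames = FALSE) <-
    log2(m)
  eff <- fitEffects(ps)
  expect_equal(unname(effectsMatrix(eff)["p1", "D1"]), 0,
               tolerance = 1e-10)
  expect_equal(unname(eff@t["p1", "D1"]), 0, tolerance = 1e-10)

  m[1, samples$is_control] <- NA
  ps2 <- PhosphoSet(m, pep, samples[, c("sample", "condition", "bio_rep",
                                        "tech_rep", "is_control")])
  suppressMessages(suppressWarnings(eff2 <- fitEffects(ps2)))
  expect_true(all(is.na(effectsMatrix(eff2)[1, ])))
  expect_false(anyNA(effectsMatrix(eff2)[-1, ]))
})

test_that("moderated statistics follow the shrinkage formula applied to an independent OLS oracle", {
  ps <- makeScreen(nPep = 30, drugs = c("D1", "D2"),
                   shift = list(D1 = 1:3), seed = 3)
  eff <- fitEffects(ps)
  lg <- SummarizedExperiment::assay(normalizeIntensities(ps), "lognorm")
  cd <- as.data.frame(SummarizedExperiment::colData(ps))
  # pool technical replicates and refit per peptide with lm()
  unit <- interaction(cd$condition, cd$bio_rep, sep = "_")
  avg <- sapply(levels(unit), function(u)
    rowMeans(lg[, unit == u, drop = FALSE]))
  ucond <- factor(sub("_.*$", "", levels(unit)),
                  levels = c("CTRL", "D1", "D2"))
  ubio <- factor(sub("^.*_", "", levels(unit)))
  d0 <- eff@prior$df; s02 <- eff@prior$s2
  for (i in c(1, 2, 15)) {
    fit <- lm(avg[i, ] ~ 0 + ucond + ubio)
    cf <- coef(fit)
    fc <- unname(cf["ucondD1"] - cf["ucondCTRL"])
    expect_equal(unname(effectsMatrix(eff)[i, "D1"]), fc,
                 tolerance = 1e-9)
    s2 <- sum(residuals(fit)^2) / df.residual(fit)
    X <- model.matrix(fit)
    ctr <- c(-1, 1, 0, 0); names(ctr) <- colnames(X)
    unscaled <- sqrt(drop(t(ctr) %*% solve(crossprod(X)) %*% ctr))
    s2post <- (d0 * s02 + df.residual(fit) * s2) / (d0 + df.residual(fit))
    expect_equal(unname(eff@t[i, "D1"]), fc / (sqrt(s2post) * unscaled),
                 tolerance = 1e-8)
  }
  # moderation shrinks each peptide's variance toward the common prior
  expect_true(all(eff@prior$df > 0, eff@prior$s2 > 0))
})

test_that("adjusted p-values are the Benjamini-Hochberg transform of the raw p-values", {
  ps <- makeScreen(nPep = 8, drugs = c("D1", "D2"),
                   shift = list(D1 = 1:2), seed = 4)
  eff <- fitEffects(ps)
  bhOracle <- function(p) {  # independent step-up implementation
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  for (d in c("D1", "D2"))
    expect_equal(unname(eff@padj[, d]), bhOracle(unname(eff@pvalue[, d])),
                 tolerance = 1e-12)
  # monotone in raw p within a condition
  for (d in c("D1", "D2")) {
    o <- order(eff@pvalue[, d])
    expect_true(all(diff(eff@padj[o, d]) >= -1e-12))
  }
  expect_true(all(eff@padj >= eff@pvalue - 1e-12))
})

test_that("mixture fitting selects one component for constant profiles and recovers planted ones", {
  f1 <- fitPeptideGmm(rep(1.7, 21), peptide = "flat")
  expect_equal(f1@K, 1L)
  expect_false(f1@booleanOk)

  set.seed(5)
  x <- c(rnorm(14, 0, 0.1), rnorm(7, 5, 0.1))
  f2 <- fitPeptideGmm(x, controlValue = 0)
  expect_equal(f2@K, 2L)
  expect_lt(abs(sort(f2@mean)[1] - 0), 0.2)
  expect_lt(abs(sort(f2@mean)[2] - 5), 0.2)
  expect_equal(f2@mean[f2@controlComponent], min(f2@mean), tolerance = 0.2)
  expect_true(f2@booleanOk)
  expect_equal(sum(f2@weight), 1, tolerance = 1e-9)
})

test_that("reported BIC equals the closed-form log-likelihood plus penalty oracle", {
  set.seed(6)
  x <- c(rnorm(12, 0, 0.3), rnorm(9, 4, 0.3))
  f <- fitPeptideGmm(x, controlValue = 0)
  ll <- loglikOracle(x[is.finite(x)], f@mean, f@sd, f@weight)
  expect_equal(f@loglik, ll, tolerance = 1e-6)
  expect_equal(f@bic, -2 * ll + f@nParams * log(f@n), tolerance = 1e-6)
})

test_that("overlap fraction matches analytic values and the numeric oracle", {
  mk <- function(mean, sd, w) new("GmmFit", peptide = "x", K = 2L,
    mean = mean, sd = sd, weight = w, loglik = 0, bic = 0,
    nParams = 5L, n = 21L, controlComponent = 1L,
    perturbedComponent = 2L, overlap = NA_real_, booleanOk = FALSE)
  expect_equal(overlapFraction(mk(c(0, 0), c(1, 1), c(0.5, 0.5))), 1,
               tolerance = 1e-6)
  expect_lt(overlapFraction(mk(c(0, 100), c(1, 1), c(0.5, 0.5))), 1e-9)
  # mu 0/2, sd 1, equal weights: min-density area = 2 Phi(-1) under the
  # default mass convention
  ov <- overlapFraction(mk(c(0, 2), c(1, 1), c(0.5, 0.5)))
  expect_equal(ov, 2 * pnorm(-1), tolerance = 1e-6)
  num <- integrate(function(z)
    pmin(0.5 * dnorm(z, 0, 1), 0.5 * dnorm(z, 2, 1)), -10, 12,
    rel.tol = 1e-10)$value
  expect_equal(overlapFraction(mk(c(0, 2), c(1, 1), c(0.5, 0.5)),
                               convention = "area"), num,
               tolerance = 1e-6)
  expect_equal(ov, num / 0.5, tolerance = 1e-6)
  expect_error(overlapFraction(f1 <- fitPeptideGmm(rep(1, 21))),
               "two-component")
})

test_that("evidence scores follow the closed-form density ratio and are antisymmetric", {
  mk <- function(ctrl = 1L) new("GmmFit", peptide = "x", K = 2L,
    mean = c(0, 2), sd = c(1, 1), weight = c(0.5, 0.5), loglik = 0,
    bic = 0, nParams = 5L, n = 21L, controlComponent = ctrl,
    perturbedComponent = 3L - ctrl, overlap = 0, booleanOk = TRUE)
  expect_equal(computeSij(mk(), 1), 0, tolerance = 1e-12)  # symmetry point
  s0 <- log10(dnorm(0, 0, 1) / dnorm(0, 2, 1))
  expect_equal(computeSij(mk(), 0), s0, tolerance = 1e-9)
  expect_equal(s0, 2 / log(10), tolerance = 1e-9)
  expect_equal(computeSij(mk(), 2), -s0, tolerance = 1e-9)
  # swapping component labels negates S
  x <- seq(-2, 4, by = 0.5)
  expect_equal(computeSij(mk(1L), x), -computeSij(mk(2L), x))
  # clamped under extreme inputs
  expect_equal(computeSij(mk(), 1e4), -10)
})

test_that("classification uses the published +/- 0.5 dead zone", {
  expect_equal(classifySij(c(-0.6, 0.6, 0, -0.5, 0.5, NA)),
               c("perturbed", "control", "undetermined", "undetermined",
                 "undetermined", NA))
})

test_that("labels recover the generating component for well-separated mixtures", {
  # |mu1 - mu2| / sd >= 6: at least 95% of draws get their own label
  set.seed(7)
  fit <- new("GmmFit", peptide = "x", K = 2L, mean = c(0, -6),
             sd = c(1, 1), weight = c(0.6, 0.4), loglik = 0, bic = 0,
             nParams = 5L, n = 21L, controlComponent = 1L,
             perturbedComponent = 2L, overlap = 0, booleanOk = TRUE)
  xc <- rnorm(500, 0, 1); xp <- rnorm(500, -6, 1)
  lc <- classifySij(computeSij(fit, xc))
  lp <- classifySij(computeSij(fit, xp))
  expect_gte(mean(lc == "control"), 0.95)
  expect_gte(mean(lp == "perturbed"), 0.95)
})

test_that("booleanization aggregates peptide evidence to sites", {
  # p1 and p2 are two ions of the same phosphosite, perturbed under D1 and
  # D2; p3 is flat; p4 is a second site on the same protein
  set.seed(8)
  conds <- c("CTRL", paste0("D", 1:4))
  lf <- rbind(p1 = c(0, -5.1, -4.9, 0.05, -0.02),
              p2 = c(0, -4.8, -5.2, -0.04, 0.03),
              p3 = c(0, 0.02, -0.03, 0.04, 0),
              p4 = c(0, 0.01, 0.02, -5.0, -5.1))
  colnames(lf) <- conds
  se <- matrix(0.2, 4, 5, dimnames = dimnames(lf))
  pep <- data.frame(peptide_id = paste0("p", 1:4),
                    protein = c("AKT1", "AKT1", "GSK3B", "AKT1"),
                    sites = c("S473", "S473", "S9", "T308"))
  eff <- new("EffectResult", logFC = lf, se = se, t = lf / 0.2,
             pvalue = matrix(0.5, 4, 5, dimnames = dimnames(lf)),
             padj = matrix(0.5, 4, 5, dimnames = dimnames(lf)),
             nobs = matrix(6, 4, 5, dimnames = dimnames(lf)),
             control = "CTRL", peptides = pep, prior = list())
  sm <- booleanizeEffects(eff)$smatrix
  expect_true(all(c("AKT1.S473", "AKT1.T308") %in%
                    rownames(siteScores(sm))))
  expect_false("GSK3B.S9" %in% rownames(siteScores(sm)))  # not bimodal
  # two ions of one site sum as independent evidence
  expect_equal(siteScores(sm)["AKT1.S473", "D1"],
               sum(sm@S[c("p1", "p2"), "D1"]))
  expect_setequal(perturbedSites(sm), c("AKT1.S473", "AKT1.T308"))
  expect_true(sm@sitePerturbed["AKT1.S473", "D1"])
  expect_false(sm@sitePerturbed["AKT1.S473", "D3"])
  # peptide labels follow the classification of their scores
  expect_equal(sm@label["p1", "D1"], "perturbed")
  expect_equal(sm@label["p1", "D3"], "control")
})
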