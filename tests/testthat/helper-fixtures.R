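# Shared fixtures, built in code.

# Minimal intensity screen: nPep peptides, conditions CTRL + drugs,
# nBio x nTech replicates; selected (peptide, drug) pairs shifted by -delta.
makeScreen <- function(nPep = 6, drugs = c("D1", "D2"), nBio = 2, nTech = 3,
                       shift = list(), delta = 5, sigma = 0.2, seed = 1) {
  set.seed(seed)
  conds <- c("CTRL", drugs)
  samples <- expand.grid(tech_rep = seq_len(nTech), bio_rep = seq_len(nBio),
                         condition = conds, stringsAsFactors = FALSE)
  samples$sample <- paste(samples$condition, samples$bio_rep,
                          samples$tech_rep, sep = "_")
  samples$is_control <- samples$condition == "CTRL"
  samples <- samples[, c("sample", "condition", "bio_rep", "tech_rep",
                         "is_control")]
  mu <- runif(nPep, 20, 26)
  m <- matrix(NA_real_, nPep, nrow(samples),
              dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    d <- rep(0, nPep)
    hit <- shift[[samples$condition[j]]]
    if (!is.null(hit)) d[hit] <- -delta
    m[, j] <- 2^(mu + d + rnorm(nPep, 0, sigma))
  }
  peptides <- data.frame(peptide_id = paste0("p", seq_len(nPep)),
                         protein = paste0("PR", seq_len(nPep)),
                         sites = paste0("S", seq_len(nPep)))
  PhosphoSet(m, peptides, samples)
}

# Hand-built background network: one target T, relay site B.S10 on kinase B,
# two measured data sites.
makeToyBackground <- function() {
  nodes <- data.frame(
    id = c("T", "B", "B.S10", "SUB1.S1", "SUB2.S2"),
    kind = c("target_kp", "kp", "site", "data_site", "data_site"),
    distance = c(0L, 2L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("T", "B.S10", "T", "B", "B"),
    target = c("B.S10", "B", "SUB1.S1", "SUB1.S1", "SUB2.S2"),
    kind = c("kps", "integrator", "kps", "kps", "kps"),
    evidence = c("experimental", "integrator", "experimental",
                 "experimental", "experimental"),
    stringsAsFactors = FALSE)
  new("BackgroundNetwork", nodes = nodes, edges = edges, targets = "T",
      limits = pathLimits(), unreachableSites = character(0))
}

# SMatrix carrying only site-level evidence (the part scoring consumes).
makeSiteEvidence <- function(siteS, cut = 0.5) {
  new("SMatrix", S = matrix(numeric(), 0, 0),
      label = matrix(character(), 0, 0),
      siteS = siteS, sitePerturbed = siteS < -cut,
      siteMap = data.frame(peptide_id = character(), site = character()),
      cut = cut)
}

# Independent quantile-normalization oracle (no ties): sort each column,
# average across columns per rank, reassign by rank.
qnOracle <- function(m) {
  ranks <- apply(m, 2, rank)
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- target[ranks[, j]]
  out
}

# Closed-form mixture log-likelihood oracle.
loglikOracle <- function(x, mean, sd, weight) {
  sum(log(vapply(x, function(xi)
    sum(weight * dnorm(xi, mean, sd)), numeric(1))))
}

# Benchmark pipeline shared by synthetic-module and acceptance tests
# (cached: it is the expensive end-to-end fixture).
benchmarkPipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    truth <- generateTruth(nKp = 20, nSites = 50, nDrugs = 4, seed = 1)
    ps <- normalizeIntensities(simulateDataset(truth, seed = 101))
    eff <- fitEffects(ps)
    bl <- booleanizeEffects(eff)
    kps <- loadKps(truth@kps)
    bg <- buildBackground(kps, targets = unique(unlist(truth@panel)),
                          perturbed = perturbedSites(bl$smatrix))
    cache <<- list(truth = truth, pset = ps, effects = eff,
                   fits = bl$fits, smatrix = bl$smatrix, kps = kps,
                   background = bg)
    cache
  }
})
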