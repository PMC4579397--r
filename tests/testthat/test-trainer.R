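# Evidence fixture for the toy background: SUB1.S1 responsive, SUB2.S2 in
# the control state under the one condition mapped to target T.
toyEvidence <- function(s1 = -1.2, s2 = 0.8) {
  makeSiteEvidence(matrix(c(s1, s2), 2, 1,
                          dimnames = list(c("SUB1.S1", "SUB2.S2"), "d1")))
}

toyModel <- function(predictS1 = TRUE, predictS2 = FALSE) {
  asg <- list(
    "SUB1.S1" = if (predictS1) list(sources = "T", gate = "SINGLE") else
      list(sources = "B", gate = "SINGLE"),
    "SUB2.S2" = if (predictS2) list(sources = "B", gate = "SINGLE") else
      list(sources = "B", gate = "SINGLE"),
    "B.S10" = if (predictS2) list(sources = "T", gate = "SINGLE") else
      list(sources = character(0), gate = "NONE"),
    "B" = if (predictS2) list(sources = "B.S10", gate = "SINGLE") else
      list(sources = character(0), gate = "NONE"))
  new("LogicModel", assignments = asg, targets = "T")
}

test_that("the score formula reproduces hand-computed values and ignores true negatives", {
  panel <- list(d1 = "T")
  sm <- toyEvidence()
  # predicts only the responsive site: score = -1.2
  expect_equal(scoreModel(toyModel(TRUE, FALSE), sm, panel)$score, -1.2)
  # predicts both: -1.2 + 0.8
  expect_equal(scoreModel(toyModel(TRUE, TRUE), sm, panel)$score, -0.4)
  # predicts neither: missed perturbation penalty +1.2
  expect_equal(scoreModel(toyModel(FALSE, FALSE), sm, panel)$score, 1.2)
  # a control-state site correctly left unpredicted contributes zero
  s <- scoreModel(toyModel(TRUE, FALSE), sm, panel)
  expect_equal(s$FP, 0)
  expect_equal(s$FN, 0)
  expect_equal(s$TP, -1.2)
  # additivity: total equals the per-condition decomposition
  s2 <- scoreModel(toyModel(TRUE, TRUE), sm, panel, sizeP = 1)
  expect_equal(s2$score,
               sum(s2$perCondition$TP + s2$perCondition$FP +
                     s2$perCondition$FN) + s2$sizePenalty)
  expect_equal(s2$sizePenalty, s2$nEdges)
})

test_that("evidence from drugs sharing a target accumulates", {
  siteS <- matrix(c(-1.2, 0.8, -1.2, 0.8), 2, 2,
                  dimnames = list(c("SUB1.S1", "SUB2.S2"), c("d1", "d2")))
  sm <- makeSiteEvidence(siteS)
  sc <- scoreModel(toyModel(TRUE, FALSE), sm, list(d1 = "T", d2 = "T"))
  expect_equal(sc$score, -2.4)
  expect_equal(nrow(sc$perCondition), 2L)
})

test_that("best-family selection applies the fractional tolerance", {
  expect_equal(selectBest(c(3, 1, 2), 0), 2L)
  expect_equal(selectBest(c(-10, -9, -5), 0.15), c(1L, 2L))  # cut -8.5
  expect_equal(selectBest(rep(2.5, 4), 0.3), 1:4)
  expect_equal(selectBest(c(5, 4, 6), 0.25), c(1L, 2L))  # cut 4 + 1 = 5
})

test_that("weight correction reproduces the published worked examples", {
  bg <- makeToyBackground()
  w <- initialWeights(bg)

  # two-edge integrator ("B" has one site here, so build one directly):
  spec <- list(node = "I", role = "integrator", sources = c("s1", "s2"))
  spec$combos <- enumerateCombinations(spec$sources, "integrator")
  spec$counts <- rep(1, 4)
  wi <- new("SamplingWeights", nodes = list(I = spec))
  fr <- list(I = list(role = "integrator",
                      combo = c("SINGLE:s1" = 0.5, "AND:s1+s2" = 0.5)))
  up <- updateWeights(wi, fr, cap = 2)
  probs <- setNames(up@nodes$I$counts / sum(up@nodes$I$counts),
                    paste(spec$combos$gate, spec$combos$sources))
  expect_equal(unname(probs[c("SINGLE s1", "SINGLE s2", "AND s1;s2",
                              "NONE ")]),
               c(2 / 6, 1 / 6, 2 / 6, 1 / 6))

  # two-edge sink at 100% best-family frequency: (0.75, 0.25)
  ss <- list(node = "S", role = "sink", sources = c("k1", "k2"))
  ss$combos <- enumerateCombinations(ss$sources, "sink")
  ss$counts <- rep(1, 2)
  ws <- new("SamplingWeights", nodes = list(S = ss))
  ups <- updateWeights(ws, list(S = list(combo = c("SINGLE:k1" = 1))),
                       cap = 2)
  expect_equal(ups@nodes$S$counts / sum(ups@nodes$S$counts), c(0.75, 0.25))

  # two-edge intermediate: edge freqs (1.0, 0.5), AND freq 0.5, cap 2 ->
  # inclusion (3/5, 2/5), gate (0.5 + 0.5) / 2
  im <- list(node = "M", role = "intermediate", sources = c("k1", "k2"),
             pEdge = c(0.5, 0.5), pAnd = 0.5)
  wm <- new("SamplingWeights", nodes = list(M = im))
  upm <- updateWeights(wm, list(M = list(edge = c(k1 = 1, k2 = 0.5),
                                         gateAND = 0.5)), cap = 2)
  expect_equal(upm@nodes$M$pEdge, c(3 / 5, 2 / 5))
  expect_equal(upm@nodes$M$pAnd, 0.5)

  # cap = 0 restores the uniform initial bins
  up0 <- updateWeights(ws, list(S = list(combo = c("SINGLE:k1" = 1))),
                       cap = 0)
  expect_equal(up0@nodes$S$counts, c(1, 1))
})

test_that("no combination exceeds the analytic cap bound after one update", {
  for (k in 2:5) for (cap in c(1, 2, 5, 20)) {
    src <- paste0("k", seq_len(k))
    spec <- list(node = "S", role = "sink", sources = src)
    spec$combos <- enumerateCombinations(src, "sink")
    spec$counts <- rep(1, k)
    w <- new("SamplingWeights", nodes = list(S = spec))
    fr <- setNames(c(1, rep(0, k - 1)), paste0("SINGLE:", src))
    up <- updateWeights(w, list(S = list(combo = fr)), cap = cap)
    p <- up@nodes$S$counts / sum(up@nodes$S$counts)
    expect_lte(max(p), (1 + cap) / (k + cap) + 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("a single-path background converges to the only consistent model", {
  bg <- makeToyBackground()
  # both sites responsive: the only model explaining the data wires
  # T -> SUB1.S1 and T -> B.S10 -> B -> SUB2.S2
  sm <- makeSiteEvidence(matrix(c(-2, -3), 2, 1,
                                dimnames = list(c("SUB1.S1", "SUB2.S2"),
                                                "d1")))
  # under the non-compounding correction a two-option node's top frequency
  # equilibrates at (1 + cap) / (2 + cap); cap = 40 puts that above 0.95
  params <- trainingParams(n = 200, generations = 10, cap = 40,
                           tolBest = 0, sizeP = 0, nRuns = 1)
  tr <- trainRun(bg, sm, list(d1 = "T"), params, seed = 42)
  fr <- tr@freqs
  expect_gt(fr[["SUB2.S2"]]$edge[["B"]], 0.95)
  expect_gt(fr[["B.S10"]]$edge[["T"]], 0.95)
  expect_gt(fr[["B"]]$edge[["B.S10"]], 0.95)
  # trajectory bookkeeping: one row per generation, family sizes within n
  expect_lte(nrow(tr@trajectory), params$generations)
  expect_true(all(tr@trajectory$family >= 1 &
                    tr@trajectory$family <= params$n))
  # selection pressure: final mean score no worse than the first
  expect_lte(tail(tr@trajectory$mean, 1), tr@trajectory$mean[1])
})

test_that("sampled training finds the exhaustively optimal score on a tiny background", {
  bg <- makeToyBackground()
  sm <- makeSiteEvidence(matrix(c(-2, 1.5), 2, 1,
                                dimnames = list(c("SUB1.S1", "SUB2.S2"),
                                                "d1")))
  panel <- list(d1 = "T")
  w <- initialWeights(bg)
  # exhaustive enumeration over all candidate models (7 combos in total)
  grids <- lapply(w@nodes, function(spec) {
    if (!is.null(spec$combos)) seq_len(nrow(spec$combos)) else
      seq_len(nrow(enumerateCombinations(spec$sources, "intermediate")))
  })
  combosOf <- function(spec) {
    if (!is.null(spec$combos)) spec$combos else
      enumerateCombinations(spec$sources, "intermediate")
  }
  grid <- expand.grid(grids)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- lapply(names(w@nodes), function(v) {
      cb <- combosOf(w@nodes[[v]])[grid[r, v], ]
      list(sources = if (nzchar(cb$sources))
        strsplit(cb$sources, ";", fixed = TRUE)[[1]] else character(0),
        gate = cb$gate)
    })
    names(asg) <- names(w@nodes)
    m <- new("LogicModel", assignments = asg, targets = "T")
    best <- min(best, scoreModel(m, sm, panel)$score)
  }
  params <- trainingParams(n = 5000, generations = 3, cap = 5,
                           tolBest = 0.3, sizeP = 0, nRuns = 1)
  tr <- trainRun(bg, sm, panel, params, seed = 7)
  expect_equal(min(tr@trajectory$best), best)
})

test_that("run combination averages frequencies and rejects mismatched runs", {
  mkRes <- function(f) new("TrainingResult",
    trajectory = data.frame(generation = 1, mean = 0, best = 0,
                            family = 1),
    freqs = list(n1 = list(role = "sink", sources = c("a", "b"),
                           combo = c("SINGLE:a" = f, "SINGLE:b" = 1 - f),
                           edge = c(a = f, b = 1 - f), gateAND = 0)),
    converged = NA_integer_, params = list(), seed = 1L)
  one <- combineRuns(list(mkRes(0.2)))
  expect_equal(one$n1$combo[["SINGLE:a"]], 0.2)
  two <- combineRuns(list(mkRes(0.2), mkRes(0.6)))
  expect_equal(two$n1$combo[["SINGLE:a"]], 0.4)
  expect_equal(two$n1$edge[["a"]], 0.4)
  same <- combineRuns(list(mkRes(0.3), mkRes(0.3)))
  expect_equal(same$n1$combo[["SINGLE:a"]], 0.3)
  bad <- mkRes(0.5)
  bad@freqs <- list(other = bad@freqs$n1)
  expect_error(combineRuns(list(mkRes(0.2), bad)), "different backgrounds")
})

test_that("consensus extraction applies the tolerance rule", {
  bg <- makeToyBackground()
  freqs <- list(
    "SUB1.S1" = list(role = "sink", sources = c("T", "B"),
                     combo = c("SINGLE:T" = 0.7, "SINGLE:B" = 0.3),
                     edge = c(T = 0.7, B = 0.3), gateAND = 0),
    "SUB2.S2" = list(role = "sink", sources = "B",
                     combo = c("SINGLE:B" = 1), edge = c(B = 1),
                     gateAND = 0),
    "B.S10" = list(role = "intermediate", sources = "T",
                   combo = c("SINGLE:T" = 0.5, "NONE" = 0.45),
                   edge = c(T = 0.5), gateAND = 0),
    "B" = list(role = "integrator", sources = "B.S10",
               combo = c("SINGLE:B.S10" = 0.55, "NONE" = 0.45),
               edge = c(B.S10 = 0.55), gateAND = 0))
  c0 <- consensusNetwork(freqs, bg, tol = 0)
  e0 <- c0@edges
  expect_equal(e0$source[e0$node == "SUB1.S1"], "T")  # argmax only
  # tol 0.2: NONE at 0.45 >= 0.8 * 0.5 for B.S10, but NONE adds no edge;
  # SUB1.S1 keeps only T (0.3 < 0.56)
  c2 <- consensusNetwork(freqs, bg, tol = 0.2)
  expect_setequal(c2@edges$source[c2@edges$node == "SUB1.S1"], "T")
  # tol 1: every nonzero input retained
  c1 <- consensusNetwork(freqs, bg, tol = 1)
  expect_setequal(c1@edges$source[c1@edges$node == "SUB1.S1"],
                  c("T", "B"))
  expect_equal(c1@edges$kind[c1@edges$node == "B"], "integrator")
  # all-zero node is omitted with a warning
  freqs$B$combo[] <- 0
  expect_warning(consensusNetwork(freqs, bg, tol = 0), "all-zero")
})

test_that("training is reproducible and independent runs derive stable sub-seeds", {
  bg <- makeToyBackground()
  sm <- makeSiteEvidence(matrix(c(-2, -3), 2, 1,
                                dimnames = list(c("SUB1.S1", "SUB2.S2"),
                                                "d1")))
  params <- trainingParams(n = 50, generations = 4, nRuns = 2)
  a <- trainModels(bg, sm, list(d1 = "T"), params, seed = 5)
  b <- trainModels(bg, sm, list(d1 = "T"), params, seed = 5)
  expect_identical(a$freqs, b$freqs)
  expect_identical(vapply(a$runs, function(r) r@seed, integer(1)),
                   vapply(b$runs, function(r) r@seed, integer(1)))
})
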