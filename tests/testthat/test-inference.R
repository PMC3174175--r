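test_that("the score is a Euclidean distance on growth rates", {
  fx <- twoGeneFixture()
  P <- uniformChain(fx$etg)
  Ix <- buildImpactMatrix(fx$etg, "x")
  Iy <- buildImpactMatrix(fx$etg, "y")
  lx <- dominantEigen(elementaryCost(P, Ix))$lambda
  ly <- dominantEigen(elementaryCost(P, Iy))$lambda

  expect_equal(scoreChain(P, list(objective(Ix, lambda = lx))), 0,
               tolerance = 1e-12)
  expect_equal(scoreChain(P, list(objective(Ix, lambda = lx + 0.02))), 0.02,
               tolerance = 1e-10)
  expect_equal(scoreChain(P, list(objective(Ix, lambda = lx + 0.03),
                                  objective(Iy, lambda = ly - 0.04))), 0.05,
               tolerance = 1e-10)
})

test_that("local search recovers hidden growth-rate vectors", {
  # known optimum: equilibrium impacts with target one -> the uniform chain
  fx <- twoGeneFixture()
  Ix <- buildImpactMatrix(fx$etg, "x")
  pt0 <- localSearch(fx$etg, list(objective(Ix, lambda = 1)), seed = 1)
  expect_true(pt0$converged)
  expect_equal(values(pt0$P), values(uniformChain(fx$etg)), tolerance = 1e-6)

  # round trips: lambdas of a hidden random chain recovered to 1e-4
  for (k in 1:20) {
    etg <- randomEtg(nProducts = 2 + (k %% 3), seed = k)   # up to 8 events
    Pstar <- random_chain(etg, seed = 1000 + k)
    prots <- paste0("g", seq_len(1 + k %% 3))
    objs <- lapply(prots, function(p) {
      I <- buildImpactMatrix(etg, p)
      objective(I, lambda = dominantEigen(elementaryCost(Pstar, I))$lambda)
    })
    pt <- localSearch(etg, objs, seed = k, tol = 1e-9, maxEval = 6000)
    expect_lt(max(abs(pt$lambdas - vapply(objs, `[[`, 0, "lambda"))), 1e-4)
    # every emitted point is row-stochastic on the support
    expect_s4_class(pt$P, "TransitionMatrix")
    expect_true(validObject(pt$P))
  }
})

test_that("source points sit strictly inside interval objectives", {
  an <- analytic_chain()
  lam_mid <- an$lambda_of_p(0.5)
  obj <- list(objective(an$impact, lo = an$lambda_of_p(0.3),
                        hi = an$lambda_of_p(0.7)))
  src <- sourcePoint(an$etg, obj, seed = 2)
  expect_true(src$interior)
  expect_equal(src$lambdas[1], (obj[[1]]$lo + obj[[1]]$hi) / 2,
               tolerance = 1e-4)

  # degenerate interval behaves as an exact search
  obj0 <- list(objective(an$impact, lo = lam_mid, hi = lam_mid))
  src0 <- sourcePoint(an$etg, obj0, seed = 2)
  expect_equal(src0$lambdas[1], lam_mid, tolerance = 1e-6)
})

test_that("boundary points match the one-parameter closed form", {
  an <- analytic_chain()
  p_lo <- 0.3; p_hi <- 0.7
  obj <- list(objective(an$impact, lo = an$lambda_of_p(p_lo),
                        hi = an$lambda_of_p(p_hi)))
  src <- sourcePoint(an$etg, obj, seed = 1)
  up <- boundaryPoint(src, 1, obj)
  dn <- boundaryPoint(src, -1, obj)
  expect_equal(up$coords, p_hi, tolerance = 1e-6)
  expect_equal(dn$coords, p_lo, tolerance = 1e-6)
  expect_true(length(up$active) >= 1 && length(dn$active) >= 1)
  # no constraint violated at the returned points
  expect_true(up$lambdas >= obj[[1]]$lo - 1e-9 &&
              up$lambdas <= obj[[1]]$hi + 1e-9)

  # intervals slacker than the reachable range: the ray stops on a face
  wide <- list(objective(an$impact, lo = an$lambda_of_p(0) / 2,
                         hi = an$lambda_of_p(1) * 2))
  srcw <- localSearch(an$etg, list(objective(an$impact,
                                             lambda = an$lambda_of_p(0.5))),
                      seed = 1)
  upw <- boundaryPoint(srcw, 1, wide)
  expect_true("simplex face" %in% upw$active)
  expect_equal(upw$coords, 1, tolerance = 1e-6)
  expect_error(boundaryPoint(src, 0, obj), "numerically zero")
})

test_that("solution sets are feasible everywhere and reduce when degenerate", {
  an <- analytic_chain()
  lam <- an$lambda_of_p(0.5)
  ss0 <- sampleSolutionSet(an$etg, list(objective(an$impact, lo = lam,
                                                  hi = lam)),
                           nDirections = 4, seed = 5)
  for (b in ss0@boundary)
    expect_equal(b$coords, ss0@source$coords, tolerance = 1e-6)

  fx <- twoGeneFixture()
  Ix <- buildImpactMatrix(fx$etg, "x")
  lam1 <- 100^(1 / 100)
  obj <- list(objective(Ix, lo = lam1 * 0.99, hi = lam1 * 1.01))
  ss <- sampleSolutionSet(fx$etg, obj, nDirections = 8, seed = 7,
                          freeRows = fx$freeRows)
  for (b in ss@boundary) {
    expect_true(b$lambdas >= obj[[1]]$lo - 1e-6 &&
                b$lambdas <= obj[[1]]$hi + 1e-6)
    expect_true(validObject(b$P))
  }
})

test_that("volume estimates agree with the one-dimensional closed form", {
  an <- analytic_chain()
  p_lo <- 0.35; p_hi <- 0.65
  obj <- list(objective(an$impact, lo = an$lambda_of_p(p_lo),
                        hi = an$lambda_of_p(p_hi)))
  ss <- sampleSolutionSet(an$etg, obj, nDirections = 4, seed = 11)
  v <- estimateVolume(ss, mcSamples = 2000, seed = 12)
  expect_equal(v$volume, p_hi - p_lo, tolerance = 1e-3 + 3 * max(v$se, 1e-6))

  # doubling the interval widths never shrinks the volume
  wide <- list(objective(an$impact, lo = an$lambda_of_p(0.2),
                         hi = an$lambda_of_p(0.8)))
  ssw <- sampleSolutionSet(an$etg, wide, nDirections = 4, seed = 11)
  vw <- estimateVolume(ssw, mcSamples = 2000, seed = 12)
  expect_gte(vw$volume, v$volume - 3 * (v$se + vw$se))

  # width-zero interval: degenerate box, zero volume
  lam <- an$lambda_of_p(0.5)
  ss0 <- sampleSolutionSet(an$etg, list(objective(an$impact, lo = lam,
                                                  hi = lam)),
                           nDirections = 3, seed = 2)
  expect_warning(v0 <- estimateVolume(ss0, mcSamples = 100, seed = 3),
                 "degenerate")
  expect_equal(v0$volume, 0)
})

test_that("sensitivity ranks transitions like the finite-difference slope", {
  # zero-probability edges cannot move the score
  fx <- twoGeneFixture()
  v <- values(uniformChain(fx$etg))
  v["y:+", ] <- 0; v["y:+", "x:+"] <- 1
  P <- TransitionMatrix(v, support(uniformChain(fx$etg)))
  Ix <- buildImpactMatrix(fx$etg, "x")
  obj <- list(objective(Ix, lambda = 1.01))
  sr <- transitionSensitivity(list(P = P), obj)
  expect_false(any(paste(sr$from, sr$to) == "y:+ y:-"))  # dropped: zero prob

  # ranking agreement with the central finite difference, up to its exact
  # ties (the two moves within a 2-edge row are collinear)
  for (k in 1:10) {
    etg <- randomEtg(3, seed = 100 + k)
    I <- buildImpactMatrix(etg, "g1")
    P <- random_chain(etg, seed = 200 + k)
    objs <- list(objective(I, lambda = dominantEigen(
      elementaryCost(uniformChain(etg), I))$lambda))
    sr <- transitionSensitivity(list(P = P), objs)
    fd <- vapply(seq_len(nrow(sr)), function(i)
      central_fd_score(P, objs, sr$from[i], sr$to[i]), 0)
    grp <- tie_groups(fd)
    top <- unique(grp[order(-fd)])[1:3]       # three best oracle groups
    sel <- grp %in% top
    r_or <- ave(rank(-fd)[sel], grp[sel])
    r_se <- ave(rank(-sr$sensitivity)[sel], grp[sel])
    rho <- if (length(unique(grp[sel])) < 2) 1 else
      suppressWarnings(stats::cor(r_or, r_se, method = "spearman"))
    expect_equal(unname(rho), 1, tolerance = 1e-12)
  }
})

test_that("sensitivity at an exact optimum falls back to raw score changes", {
  fx <- twoGeneFixture()
  Ix <- buildImpactMatrix(fx$etg, "x")
  obj <- list(objective(Ix, lambda = 1))
  pt <- localSearch(fx$etg, obj, seed = 1, tol = 1e-10)
  sr <- transitionSensitivity(pt, obj)
  expect_false(attr(sr, "normalized"))
  expect_true(all(diff(sr$sensitivity) <= 0))   # descending ranking
  expect_true(all(sr$sensitivity >= 0))
})

test_that("predicted distributions integrate the solution set", {
  an <- analytic_chain()
  lam <- an$lambda_of_p(0.5)
  obj0 <- list(objective(an$impact, lo = lam, hi = lam))
  ss0 <- sampleSolutionSet(an$etg, obj0, nDirections = 2, seed = 1)
  pd0 <- predictDistribution(ss0, an$impact, nSamples = 20, seed = 2)
  expect_equal(pd0$lambdas, rep(lam, pd0$accepted), tolerance = 1e-5)

  # equal impact matrices give identical predictions
  fx <- twoGeneFixture()
  Ix <- buildImpactMatrix(fx$etg, "x")
  lam1 <- 100^(1 / 100)
  obj <- list(objective(Ix, lo = lam1 * 0.98, hi = lam1 * 1.02))
  ss <- sampleSolutionSet(fx$etg, obj, nDirections = 6, seed = 3,
                          freeRows = fx$freeRows)
  twin <- new("ImpactMatrix", values = values(Ix), support = support(Ix),
              protein = "x2", s = Ix@s, d = Ix@d, rho = Ix@rho)
  p1 <- predictDistribution(ss, Ix, nSamples = 50, seed = 4)
  p2 <- predictDistribution(ss, twin, nSamples = 50, seed = 4)
  expect_identical(p1$lambdas, p2$lambdas)

  # constrained vs unconstrained growth-rate distributions differ
  Iy <- buildImpactMatrix(fx$etg, "y")
  cons <- predictDistribution(ss, Iy, nSamples = 200, seed = 5)
  set.seed(6)
  free_lam <- vapply(1:200, function(i) {
    P <- random_chain(fx$etg, seed = 10000 + i)
    dominantEigen(elementaryCost(P, Iy))$lambda
  }, 0)
  ks <- suppressWarnings(stats::ks.test(cons$lambdas, free_lam))
  crit <- 1.628 * sqrt((length(cons$lambdas) + 200) /
                       (length(cons$lambdas) * 200))
  expect_gt(unname(ks$statistic), crit)
})
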