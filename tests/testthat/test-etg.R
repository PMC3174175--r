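test_that("event graphs canonicalize, deduplicate and validate", {
  etg <- EventTransitionGraph(
    from = c("b:+", "a:-", "a:-", "sig"),
    to = c("a:-", "b:+", "b:+", "a:-"))
  expect_equal(eventLabels(etg), c("a:-", "b:+", "sig"))  # aux last
  expect_equal(nrow(edgeTable(etg)), 3)                   # duplicate collapsed
  expect_equal(eventTable(etg)$kind, c("transcriptional", "transcriptional",
                                       "auxiliary"))
  expect_error(new("EventTransitionGraph",
                   events = eventTable(etg),
                   edges = data.frame(from = 1L, to = 99L,
                                      condition = NA_character_),
                   conditions = character()),
               "out of range")
})

test_that("a state-graph toggle yields the two-event alternating graph", {
  stg <- data.frame(from = c("s0", "s1"), to = c("s1", "s0"),
                    changed_var = "x", direction = c("+", "-"))
  etg <- etgFromStateGraph(stg)
  ed <- edgeTable(etg)
  expect_setequal(paste(ed$from, ed$to), c("x:+ x:-", "x:- x:+"))
})

test_that("state-graph derivation matches the length-2 path definition", {
  # 3-state chain with a return edge
  stg <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                    changed_var = c("x", "y", "x"),
                    direction = c("+", "+", "-"))
  ed <- edgeTable(etgFromStateGraph(stg))
  expect_setequal(paste(ed$from, ed$to), c("x:+ y:+", "y:+ x:-"))

  # random state graphs vs brute-force enumeration of all length-2 paths
  for (seed in 1:5) {
    set.seed(seed)
    ns <- sample(10:50, 1)
    nt <- sample(ns:(2 * ns), 1)
    stg <- data.frame(from = paste0("s", sample(ns, nt, replace = TRUE)),
                      to = paste0("s", sample(ns, nt, replace = TRUE)),
                      changed_var = sample(c("u", "v", "w"), nt, replace = TRUE),
                      direction = sample(c("+", "-"), nt, replace = TRUE))
    stg <- stg[stg$from != stg$to, , drop = FALSE]
    ev <- paste0(stg$changed_var, ":", stg$direction)
    want <- character(0)
    for (i in seq_len(nrow(stg)))
      for (j in seq_len(nrow(stg)))
        if (stg$to[i] == stg$from[j]) want <- c(want, paste(ev[i], ev[j]))
    want <- sort(unique(want))
    if (!length(want)) {
      expect_error(etgFromStateGraph(stg), "length-2")
    } else {
      ed <- edgeTable(etgFromStateGraph(stg))
      expect_identical(sort(paste(ed$from, ed$to)), want)
    }
  }
})

test_that("malformed state graphs are rejected", {
  stg <- data.frame(from = "a", to = "b", changed_var = "x", direction = "up")
  expect_error(etgFromStateGraph(stg), "direction")
  stg2 <- data.frame(from = c("a", "b"), to = c("b", "a"),
                     levels = c("0,0", "1,1"),
                     changed_var = "x", direction = c("+", "-"))
  expect_error(etgFromStateGraph(stg2), "exactly one variable")
})

test_that("condition filtering keeps unconditional edges and errors on typos", {
  plain <- twoGeneFixture()$etg
  expect_identical(edgeTable(applyCondition(plain, "anything")),
                   edgeTable(plain))  # no conditional edge anywhere: no-op

  cs <- carbonStarvationFixture()$etg
  expect_equal(nrow(edgeTable(cs)), 22)
  starv <- applyCondition(cs, "starvation")
  expect_equal(nrow(edgeTable(starv)), 20)
  expect_equal(nrow(edgeTable(applyCondition(cs, "no-starvation"))), 22)
  expect_error(applyCondition(cs, "starvationn"), "unknown condition")
})

test_that("uniform chains split mass equally and reject dead ends", {
  fx <- twoGeneFixture()
  P <- uniformChain(fx$etg)
  expect_true(all(values(P)[support(P)] == 0.5))
  expect_equal(unname(rowSums(values(P))), rep(1, 4))

  dead <- EventTransitionGraph(from = c("a:+", "a:-"), to = c("a:-", "b:+"))
  expect_error(uniformChain(dead), "dead-end.*b:\\+")
})

test_that("stationary distributions solve pi P = pi", {
  # doubly stochastic 4-event chain: uniform
  fx <- twoGeneFixture()
  P <- uniformChain(fx$etg)
  expect_equal(unname(stationaryDistribution(P)), rep(0.25, 4),
               tolerance = 1e-12)

  # 2-event deterministic alternation
  v <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a:+", "a:-"), c("a:+", "a:-")))
  expect_equal(unname(stationaryDistribution(TransitionMatrix(v))),
               c(0.5, 0.5))

  # 3-event chain, solved by hand from the balance equations:
  # pi1 = pi2/2 + pi3, pi2 = pi1, pi3 = pi2/2  =>  (0.4, 0.4, 0.2)
  lab <- c("e1", "e2", "e3")
  v <- matrix(c(0, 1, 0, 0.5, 0, 0.5, 1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(lab, lab))
  expect_equal(unname(stationaryDistribution(TransitionMatrix(v))),
               c(0.4, 0.4, 0.2), tolerance = 1e-12)

  # property: 100 random irreducible chains, residual below 1e-10
  for (k in 1:100) {
    etg <- randomEtg(nProducts = 2 + k %% 5, seed = 3000 + k)
    P <- random_chain(etg, seed = 4000 + k)
    pi <- stationaryDistribution(P)
    expect_lt(max(abs(drop(pi %*% values(P)) - pi)), 1e-10)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
})

test_that("minimality diagnoses period and connectivity", {
  two_cycle <- TransitionMatrix(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
    dimnames = list(c("a:+", "a:-"), c("a:+", "a:-"))))
  rep1 <- checkMinimality(two_cycle)
  expect_true(rep1$irreducible)
  expect_false(rep1$aperiodic)
  expect_equal(rep1$period, 2L)

  self_loop <- analytic_chain()$etg
  rep2 <- checkMinimality(uniformChain(self_loop))
  expect_true(rep2$irreducible && rep2$aperiodic)
  expect_equal(rep2$period, 1L)

  lab <- c("a:+", "a:-", "b:+", "b:-")
  v <- matrix(0, 4, 4, dimnames = list(lab, lab))
  v[1, 2] <- v[2, 1] <- v[3, 4] <- v[4, 3] <- 1
  rep3 <- checkMinimality(TransitionMatrix(v))
  expect_false(rep3$irreducible)
})

test_that("restriction renormalizes rows and flags emptied rows", {
  fx <- carbonStarvationFixture()
  P <- uniformChain(fx$etg)  # on all 22 edges
  P2 <- restrictRenormalize(P, fx$etg, condition = "starvation")
  expect_equal(unname(rowSums(values(P2))), rep(1, 11), tolerance = 1e-12)
  expect_equal(sum(support(P2)), 20)

  # removing a zero-probability edge leaves the values unchanged
  etg <- twoGeneFixture()$etg
  P <- uniformChain(etg)
  v <- values(P)
  v["y:+", ] <- 0; v["y:+", "x:+"] <- 1   # mass off the y:+ -> y:- edge
  P3 <- TransitionMatrix(v, support(P))
  ed <- edgeTable(etg)
  drop6 <- !(ed$from == "y:+" & ed$to == "y:-")
  sub <- EventTransitionGraph(from = ed$from[drop6], to = ed$to[drop6])
  expect_equal(values(restrictRenormalize(P3, sub)), {
    v2 <- v; v2["y:+", "y:-"] <- 0; v2
  })
  # a row stripped of all its mass is re-spread equally
  P4 <- restrictRenormalize(P, sub)
  expect_equal(values(P4)["y:+", "x:+"], 1)
  # random chains: all rows re-sum to one after random edge removal
  for (k in 1:10) {
    etg_k <- randomEtg(3, seed = 500 + k)
    P_k <- random_chain(etg_k, seed = 600 + k)
    ed <- edgeTable(etg_k)
    # drop one edge from a row with out-degree >= 2, keeping minimality a non-issue
    outdeg <- table(ed$from)
    cand <- which(outdeg[ed$from] >= 2)
    drop <- cand[sample.int(length(cand), 1)]
    etg2 <- EventTransitionGraph(from = ed$from[-drop], to = ed$to[-drop])
    if (nEvents(etg2) < nEvents(etg_k)) next
    P2 <- restrictRenormalize(P_k, etg2)
    expect_equal(unname(rowSums(values(P2))), rep(1, nEvents(etg_k)),
                 tolerance = 1e-12)
  }
})
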