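#' @include inference.R
NULL

#' Two-gene tutorial fixture
#'
#' The minimal event transition graph used to illustrate the framework:
#' two genes, four events, eight edges (two out-edges per event), and a
#' transition matrix with exactly two unknowns carried by the rows of the
#' second gene's events. The wiring is symmetric under exchanging the two
#' genes, so both proteins calibrate to the same equilibrium coefficients.
#' It is a reconstruction: the published graph and matrix are only
#' available graphically, and this is the symmetric two-out-edge wiring on
#' which the tutorial's growth specification (a hundredfold rise of the
#' mean protein x concentration in one hundred iterations from an
#' unsynchronized population) is attainable.
#'
#' @param rho passive rate used for the impact configurations.
#' @return list with \code{etg}, \code{freeRows} (labels of the rows with
#'   free parameters) and \code{config} (per-protein passive rates).
#' @export
twoGeneFixture <- function(rho = 0.95) {
  stopifnot(rho > 0, rho <= 1)
  etg <- EventTransitionGraph(
    from = c("x:+", "x:+", "x:-", "x:-", "y:+", "y:+", "y:-", "y:-"),
    to   = c("x:-", "y:+", "y:+", "y:-", "y:-", "x:+", "x:+", "x:-"))
  stopifnot(nEvents(etg) == 4, nrow(etg@edges) == 8)
  minim <- checkMinimality(uniformChain(etg))
  stopifnot(minim$irreducible, minim$aperiodic)
  list(etg = etg, freeRows = c("y:+", "y:-"),
       config = list(x = list(passive_rate = rho),
                     y = list(passive_rate = rho)))
}

#' Escherichia coli carbon-starvation fixture (synthetic reconstruction)
#'
#' An 11-event, 22-edge event transition graph for the carbon-starvation
#' response: slope events for fis, crp, cya, gyrAB and topA plus one
#' auxiliary "complex" event (the Crp-Cya-cAMP complex). The carbon
#' starvation signal is modeled as the environmental condition: two edges
#' are tagged \code{"no-starvation"} and are therefore absent under the
#' \code{"starvation"} condition. The exact arrow set of the published
#' graph is not machine-readable; this reconstruction satisfies the
#' printed structural facts (11 nodes, 22 edges, 2 condition-dependent
#' transitions, minimal under both conditions) and the described
#' interactions: Fis represses crp (and cya), the supercoiling homeostasis
#' loop couples fis, gyrAB and topA, and the complex forms downstream of
#' crp/cya and represses fis. The crp and cya events occupy exchangeable
#' positions (a graph automorphism swaps them), so the two proteins share
#' the same predicted behavior over the solution set. Structural
#' self-checks run at build time.
#'
#' @param rho passive rate for the impact configurations (default 0.95).
#' @param half_life_min shortest amino-acid half-life used to document the
#'   configuration (minutes).
#' @param delta mean transition duration in minutes; the default 0.35
#'   follows the 20-iterations-per-7-minutes correspondence of the case
#'   study.
#' @return list with \code{etg}, \code{conditions}
#'   (\code{c("starvation", "no-starvation")}) and \code{config}.
#' @export
carbonStarvationFixture <- function(rho = 0.95, half_life_min = 2,
                                    delta = 0.35) {
  ns <- "no-starvation"
  edges <- rbind(
    c("fis:+",    "crp:-",    NA),  # Fis represses crp
    c("fis:-",    "crp:+",    NA),
    c("fis:+",    "gyrAB:-",  NA),  # Fis represses gyrAB
    c("fis:-",    "gyrAB:+",  NA),
    c("fis:+",    "topA:+",   NA),  # Fis activates topA
    c("fis:-",    "topA:-",   NA),
    c("fis:+",    "cya:-",    NA),  # Fis represses cya
    c("fis:-",    "cya:+",    NA),
    c("gyrAB:+",  "fis:+",    NA),  # supercoiling activates fis
    c("gyrAB:-",  "fis:-",    NA),
    c("topA:+",   "fis:-",    NA),  # relaxation represses fis
    c("topA:-",   "fis:+",    NA),
    c("topA:+",   "gyrAB:+",  NA),  # relaxation induces gyrAB
    c("crp:+",    "complex",  NA),  # complex formation
    c("cya:+",    "complex",  NA),
    c("complex",  "fis:-",    NA),  # complex represses fis
    c("complex",  "cya:-",    NA),  # complex represses cya and crp
    c("complex",  "crp:-",    NA),
    c("crp:-",    "fis:+",    NA),  # less complex derepresses fis
    c("cya:-",    "fis:+",    NA),
    c("complex",  "crp:+",    ns),  # signal-dependent activations
    c("complex",  "cya:+",    ns))
  etg <- EventTransitionGraph(from = edges[, 1], to = edges[, 2],
                              condition = edges[, 3],
                              conditions = c("starvation", ns))
  # structural self-checks against the printed counts
  stopifnot(nEvents(etg) == 11, nrow(etg@edges) == 22,
            sum(!is.na(etg@edges$condition)) == 2)
  for (cond in c("starvation", ns)) {
    minim <- checkMinimality(uniformChain(etg, condition = cond))
    stopifnot(minim$irreducible, minim$aperiodic)
  }
  stopifnot(nrow(applyCondition(etg, "starvation")@edges) == 20)
  proteins <- c("fis", "crp", "cya", "gyrAB", "topA")
  config <- lapply(proteins, function(p)
    list(passive_rate = rho, half_life_min = half_life_min, delta = delta))
  names(config) <- proteins
  list(etg = etg, conditions = c("starvation", ns), config = config)
}

#' Fis concentration series fixture (synthetic beyond the printed ratio)
#'
#' A two-segment series reproducing the documented shape: a tenfold rise
#' over the first 80 minutes (stationary growth phase under carbon
#' starvation), then an exponential decline (exponential growth phase).
#' Only the 10-fold / 80-minute ratio and the subsequent decrease are
#' anchored in the literature; point placement and the decline rate are
#' synthetic.
#'
#' @param K0 initial concentration (arbitrary units).
#' @return list with \code{series} (a \code{\link{proteinSeries}}) and
#'   \code{cutpoints} (\code{c(0, 80, 140)}).
#' @export
fisSeriesFixture <- function(K0 = 1) {
  cut <- c(0, 80, 140)
  f1 <- 10^(1 / 80)          # tenfold over 80 minutes
  f2 <- (1 / 5)^(1 / 60)     # synthetic decline
  t1 <- c(0, 40, 80)
  t2 <- c(100, 120, 140)
  c1 <- K0 * f1^t1
  c2 <- (K0 * 10) * f2^(t2 - 80)
  list(series = proteinSeries(c(t1, t2), c(c1, c2), protein = "fis"),
       cutpoints = cut)
}

#' Random minimal event transition graph
#'
#' Generates property-test graphs: \code{nProducts} products with both
#' slope events, a random Hamiltonian cycle over all events for strong
#' connectivity, extra random edges, and a guaranteed odd cycle (one
#' 2-cycle plus one triangle chord) for aperiodicity. The construction is
#' rejected and redrawn until the uniform chain is minimal.
#'
#' @param nProducts number of products (events = 2 * nProducts).
#' @param extraEdges additional random edges beyond the base cycle.
#' @param seed RNG seed.
#' @return an \linkS4class{EventTransitionGraph}.
#' @export
randomEtg <- function(nProducts = 3, extraEdges = 2 * nProducts, seed = 1) {
  stopifnot(nProducts >= 2)
  set.seed(seed)
  labels <- as.vector(outer(paste0("g", seq_len(nProducts)), c(":+", ":-"),
                            paste0))
  n <- length(labels)
  for (try in 1:50) {
    ord <- sample(n)
    from <- labels[ord]
    to <- labels[ord[c(2:n, 1)]]
    # chord skipping one cycle node yields coprime cycle lengths (n, n-1)
    from <- c(from, labels[ord[1]])
    to <- c(to, labels[ord[3]])
    for (k in seq_len(extraEdges)) {
      i <- sample(n, 1); j <- sample(n, 1)
      if (i != j) { from <- c(from, labels[i]); to <- c(to, labels[j]) }
    }
    etg <- EventTransitionGraph(from = from, to = to)
    if (nEvents(etg) < n) next
    minim <- checkMinimality(etg)
    if (!minim$irreducible || !minim$aperiodic) next
    # the equilibrium calibration must exist for every product (it does not
    # when production and degradation events only occur paired on cycles)
    ok <- all(vapply(paste0("g", seq_len(nProducts)), function(p) {
      !inherits(tryCatch(buildImpactMatrix(etg, p), error = identity),
                "error")
    }, TRUE))
    if (ok) return(etg)
  }
  stop("failed to generate a minimal random graph")
}

#' Synthetic protein series from a generating accumulation rule
#'
#' Emits \code{K0 * lambda^(t/delta) * exp(noise)} with centered Gaussian
#' log-noise of standard deviation \code{sigma} per point, mirroring the
#' log-normal law of the accumulated cost in the permanent regime.
#'
#' @param lambda per-transition growth factor.
#' @param delta mean transition duration, minutes.
#' @param times sampling times, minutes (strictly increasing).
#' @param K0 initial concentration.
#' @param sigma log-noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param protein identifier.
#' @return a \code{\link{proteinSeries}}.
#' @export
syntheticSeries <- function(lambda, delta, times, K0 = 1, sigma = 0,
                            seed = 1, protein = "synthetic") {
  stopifnot(sigma >= 0, lambda > 0, delta > 0)
  set.seed(seed)
  noise <- if (sigma > 0) stats::rnorm(length(times), 0, sigma) else 0
  proteinSeries(times, K0 * lambda^(times / delta) * exp(noise), protein)
}
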