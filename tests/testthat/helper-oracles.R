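# shared oracles and generators, independent of the code paths they check

# exhaustive path enumeration: E[prod of impacts along n-step trajectories]
# and E[(prod)^2], by direct summation over all paths
brute_force_moments <- function(P, I, v0, n) {
  pv <- values(P); iv <- values(I)
  m <- nrow(pv)
  end <- seq_len(m); probs <- v0; costs <- rep(1, m)
  for (step in seq_len(n)) {
    ne <- integer(0); np <- numeric(0); nc <- numeric(0)
    for (i in seq_along(end)) {
      if (probs[i] == 0) next
      for (nxt in which(pv[end[i], ] > 0)) {
        ne <- c(ne, nxt)
        np <- c(np, probs[i] * pv[end[i], nxt])
        nc <- c(nc, costs[i] * iv[end[i], nxt])
      }
    }
    end <- ne; probs <- np; costs <- nc
  }
  list(mean = sum(probs * costs), second = sum(probs * costs^2))
}

# random row-stochastic matrix on the support of a graph's uniform chain
random_chain <- function(etg, seed) {
  set.seed(seed)
  s <- support(uniformChain(etg))
  v <- s * 0
  for (r in seq_len(nrow(s))) {
    out <- which(s[r, ])
    w <- stats::rgamma(length(out), 1)
    v[r, out] <- w / sum(w)
  }
  TransitionMatrix(v, s)
}

# central finite difference of the inference score along the renormalized
# multiplicative move of one edge (the direction the sensitivity probes)
central_fd_score <- function(P, objectives, from, to, h = 1e-4) {
  s <- support(P)
  f <- vapply(c(1 + h, 1 - h), function(m) {
    v2 <- values(P)
    v2[from, to] <- v2[from, to] * m
    v2[from, ] <- v2[from, ] / sum(v2[from, ])
    scoreChain(TransitionMatrix(v2, s), objectives)
  }, 0)
  abs(f[1] - f[2]) / (2 * h)
}

# average ranks after collapsing values equal within a relative tolerance
# (moves within one 2-edge row are collinear, so their derivative magnitudes
# tie exactly; numerics separate them at ~1e-10)
tie_groups <- function(v, rel_tol = 1e-6) {
  ord <- order(-v)
  g <- integer(length(v))
  gid <- 1L
  g[ord[1]] <- gid
  for (i in seq_along(ord)[-1]) {
    if (v[ord[i - 1]] - v[ord[i]] > rel_tol * max(v, 1e-300)) gid <- gid + 1L
    g[ord[i]] <- gid
  }
  g
}

# two-state chain with a self-loop: the one-free-parameter analytic case
# (impacts overridden since no passive edge exists on this support)
analytic_chain <- function(s_active = 2) {
  etg <- EventTransitionGraph(from = c("a:+", "a:+", "a:-"),
                              to = c("a:+", "a:-", "a:+"))
  I <- buildImpactMatrix(etg, "a", overrides = list(s = s_active))
  lambda_of_p <- function(p) {
    sv <- s_active; dv <- 1 / s_active
    (p * sv + sqrt(p^2 * sv^2 + 4 * (1 - p))) / 2  # root of l^2 - p s l - (1-p) d s
  }
  list(etg = etg, impact = I, lambda_of_p = lambda_of_p)
}
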