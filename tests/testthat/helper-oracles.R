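# Independent oracles and fixture builders shared across test files.

# Event-level Monte-Carlo oracle for the screen-detected fraction.
# A cancer's preclinical onset falls uniformly within a screening round
# (time tau to the next screen ~ U(0, u)); the sojourn in the screen-
# detectable phase is Exp(lambda); screens occur at tau, tau + u, ... with
# independent per-screen sensitivity D. The cancer is screen-detected iff
# some screen before symptomatic surfacing succeeds.
mc_screen_detected <- function(params, u, n = 1e5) {
  tau <- stats::runif(n, 0, u)
  sojourn <- stats::rexp(n, params$lambda_rate)
  n_screens <- ifelse(sojourn > tau, floor((sojourn - tau) / u) + 1, 0)
  detected <- stats::rgeom(n, params$sensitivity) < n_screens
  phat <- mean(detected)
  list(phat = phat, se = sqrt(phat * (1 - phat) / n))
}

# Random allocation instance. separable = TRUE gives p_kj = r_k * c_j with
# effectiveness ordered by cost (the model's structure); FALSE gives an
# arbitrary non-negative p for solver stress-testing.
random_instance <- function(K, m, separable = TRUE) {
  r <- sort(stats::runif(K, 0.001, 0.1))
  h <- sort(stats::runif(m, 1, 6))
  p <- if (separable) {
    eff <- sort(stats::runif(m, 0.2, 0.5), decreasing = TRUE)
    outer(r, eff)
  } else {
    matrix(stats::runif(K * m, 0, 0.1), K, m)
  }
  budget <- K * stats::runif(1, min(h), max(h))
  regs <- lapply(seq_len(m), function(j)
    regimen(6 / h[j], label = paste0("R", j), cost = h[j]))
  build_problem(risk_quantiles(r), regs, nh_params(), budget = budget,
                p_matrix = p)
}

# Fully independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# system python. Returns the optimal objective, or NA when infeasible.
scipy_lp_objective <- function(problem) {
  script <- file.path(tempdir(), "lp_oracle.py")
  if (!file.exists(script)) {
    writeLines(c(
      "import sys, json",
      "import numpy as np",
      "from scipy.optimize import linprog",
      "d = json.load(open(sys.argv[1]))",
      "p = np.array(d['p']); h = np.array(d['h']); H = d['H']",
      "K, m = p.shape",
      "A_eq = np.zeros((K, K * m))",
      "for k in range(K): A_eq[k, k * m:(k + 1) * m] = 1",
      "res = linprog(p.ravel(), A_ub=h.ravel()[None, :], b_ub=[H],",
      "              A_eq=A_eq, b_eq=np.ones(K), bounds=(0, 1),",
      "              method='highs')",
      "print(json.dumps({'ok': bool(res.success),",
      "                  'fun': res.fun if res.success else None}))"),
      script)
  }
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(p = problem$p, h = problem$h, H = problem$budget),
                       inp, digits = NA, auto_unbox = TRUE)
  out <- system2("python", c(script, inp), stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  if (isTRUE(res$ok)) res$fun else NA_real_
}

# One-row oracle: cheapest objective of a single simplex mixture under a
# per-person budget, by fine grid over regimen pairs.
lp_mix_oracle <- function(cj, hj, hbar) {
  best <- Inf
  m <- length(cj)
  for (j1 in seq_len(m)) for (j2 in seq_len(m)) for (t in seq(0, 1, 0.001)) {
    if (t * hj[j1] + (1 - t) * hj[j2] <= hbar + 1e-12)
      best <- min(best, t * cj[j1] + (1 - t) * cj[j2])
  }
  best
}

# Toy 5-quantile distribution with unit-spaced score boundaries, for
# hand-checkable threshold extraction.
toy_quantiles <- function() {
  risk_quantiles(c(0.01, 0.02, 0.03, 0.04, 0.05),
                 boundaries = seq(0, 0.5, by = 0.1))
}

expect_feasible <- function(sol, problem, tol = 1e-7) {
  expect_equal(unname(rowSums(sol$x)), rep(1, problem$K), tolerance = tol)
  expect_true(all(sol$x >= -tol) && all(sol$x <= 1 + tol))
  expect_lte(sum(sol$x * problem$h), problem$budget + tol * (1 + problem$budget))
}
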