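test_that("build_problem assembles costs, budget and the p matrix", {
  q <- risk_quantiles(rep(0.02, 100))
  pr <- build_problem(q, regimen_set(c(1, 3)), nh_params(),
                      baseline_label = "3y")
  expect_equal(unname(pr$h[1, ]), c(6, 2))
  expect_equal(pr$budget, 200)   # triennial-equivalent at K = 100
  expect_equal(regimen(4)$cost, 1.5)
  # p composes the natural-history model column-wise
  expect_equal(unname(pr$p[, "1y"]),
               advanced_risk(q$mean_risk, nh_params(), regimen(1)))
  expect_error(build_problem(q, list(), nh_params(), budget = 10),
               "non-empty")
  expect_error(build_problem(q, regimen_set(3), nh_params()), "budget")
  # single regimen: feasible iff K * h <= H
  pr1 <- build_problem(risk_quantiles(rep(0.01, 5)), regimen_set(3),
                       nh_params(), budget = 10)
  expect_equal(solve_lp(pr1)$status, "optimal")
  pr1$budget <- 9.9
  expect_equal(solve_lp(pr1)$status, "infeasible")
})

test_that("solve_lp is exact on the unconstrained and symmetric limits", {
  set.seed(21)
  pr <- random_instance(8, 4)
  pr$budget <- 8 * max(pr$h) + 1          # budget can buy the best for all
  sol <- solve_lp(pr)
  best <- apply(pr$p, 1, min)
  expect_equal(sol$objective, sum(best), tolerance = 1e-10)
  # equal risks: optimal objective is unique however ties are broken
  q <- risk_quantiles(rep(0.05, 6))
  pr2 <- build_problem(q, regimen_set(c(1, 3, 6)), nh_params(),
                       baseline_label = "3y")
  s1 <- solve_lp(pr2)
  expect_feasible(s1, pr2)
  # by symmetry the optimum equals the best uniform budget-feasible mixture
  cj <- pr2$p[1, ]; hj <- pr2$h[1, ]
  mix <- lp_mix_oracle(cj, hj, pr2$budget / 6)
  expect_equal(s1$objective, 6 * mix, tolerance = 1e-8)
})

test_that("solve_lp matches the grid brute force on the 3-quantile instance", {
  q <- risk_quantiles(c(0.001, 0.01, 0.05))
  pr <- build_problem(q, regimen_set(c(1, 3, 6)), nh_params(),
                      baseline_label = "3y")
  lp <- solve_lp(pr)
  bf <- brute_force(pr, grid_step = 0.01, mode = "lp")
  expect_feasible(lp, pr)
  expect_gte(bf$objective, lp$objective - 1e-9)
  expect_lte(bf$objective - lp$objective, 0.01 * max(pr$p))
})

test_that("solve_lp agrees with brute force and scipy on random instances", {
  set.seed(77)
  for (i in 1:25) {
    K <- sample(2:6, 1); m <- sample(2:3, 1)
    pr <- random_instance(K, m, separable = i %% 2 == 0)
    lp <- solve_lp(pr)
    bf <- brute_force(pr, grid_step = 0.01, mode = "lp")
    expect_equal(lp$status, bf$status)
    if (lp$status == "optimal") {
      expect_feasible(lp, pr)
      expect_gte(bf$objective, lp$objective - 1e-8)
      expect_lte(bf$objective - lp$objective, 0.01 * max(pr$p) + 1e-8)
    }
  }
})

test_that("solve_lp matches scipy linprog on a batch of instances", {
  set.seed(123)
  for (i in 1:8) {
    pr <- random_instance(sample(3:10, 1), sample(2:4, 1),
                          separable = i %% 2 == 0)
    ref <- scipy_lp_objective(pr)
    lp <- solve_lp(pr)
    if (is.na(ref)) {
      expect_equal(lp$status, "infeasible")
    } else {
      expect_equal(lp$objective, ref, tolerance = 1e-7)
    }
  }
})

test_that("solve_ip matches exhaustive enumeration on the frozen toy", {
  # K = 2, m = 2, costs (2, 1), H = 3; enumeration over the 4 binary
  # assignments: (1,1) costs 4 infeasible; (1,2) obj 0.4; (2,1) obj 0.7;
  # (2,2) obj 0.8 -> optimum (1,2) with objective 0.4
  q <- risk_quantiles(c(0.02, 0.03))
  regs <- list(regimen(3, "A", cost = 2), regimen(6, "B", cost = 1))
  p <- rbind(c(0.1, 0.5), c(0.2, 0.3))
  pr <- build_problem(q, regs, nh_params(), budget = 3, p_matrix = p)
  ip <- solve_ip(pr)
  expect_equal(ip$objective, 0.4)
  expect_equal(unname(ip$x), rbind(c(1, 0), c(0, 1)))
  lp <- solve_lp(pr)
  expect_lte(lp$objective, ip$objective + 1e-12)  # relaxation bound
})

test_that("branch-and-bound and enumeration routes agree; LP bounds IP", {
  set.seed(55)
  for (i in 1:10) {
    pr <- random_instance(sample(2:6, 1), sample(2:3, 1),
                          separable = i %% 2 == 0)
    enum <- solve_ip(pr)                    # enumeration route
    bb <- solve_ip(pr, enum_limit = 1)      # branch-and-bound route
    bf <- brute_force(pr, mode = "ip")      # oracle
    expect_equal(enum$status, bf$status)
    expect_equal(bb$status, bf$status)
    if (enum$status == "optimal") {
      expect_equal(enum$objective, bf$objective, tolerance = 1e-12)
      expect_equal(bb$objective, bf$objective, tolerance = 1e-9)
      expect_lte(solve_lp(pr)$objective, enum$objective + 1e-9)
    }
  }
  # budget large enough: IP and LP coincide
  pr <- random_instance(5, 3)
  pr$budget <- 5 * max(pr$h) + 1
  expect_equal(solve_ip(pr)$objective, solve_lp(pr)$objective,
               tolerance = 1e-12)
})

test_that("brute force respects its preconditions and trivial cases", {
  expect_error(brute_force(random_instance(9, 3)), "refuses")
  # K = 1: picks the cheapest-objective affordable regimen
  q <- risk_quantiles(0.05)
  regs <- list(regimen(1, "A", cost = 6), regimen(6, "B", cost = 1))
  p <- matrix(c(0.01, 0.04), 1)
  pr <- build_problem(q, regs, nh_params(), budget = 2, p_matrix = p)
  expect_equal(brute_force(pr, mode = "ip")$objective, 0.04)
  pr$budget <- 10
  expect_equal(brute_force(pr, mode = "ip")$objective, 0.01)
})

test_that("canonicalize yields cost-monotone contiguous optima", {
  q <- risk_quantiles(c(0.01, 0.01, 0.05))  # two equal-risk quantiles
  regs <- list(regimen(1, "1y"), regimen(6, "6y"))
  pr <- build_problem(q, regs, nh_params(), budget = 13)
  # swapped optimum: expensive regimen on the first of two equal risks
  x <- rbind(c(1, 0), c(0, 1), c(1, 0))
  colnames(x) <- pr$labels
  a <- screenopt:::new_assignment(x, sum(x * pr$p), "lp", "optimal", pr,
                                  sum(x * pr$h))
  ca <- canonicalize(a, q)
  expect_equal(ca$objective, a$objective, tolerance = 1e-12)
  # intensity non-increasing in risk rank: 1y on k=3 and k=2, 6y on k=1
  expect_equal(unname(ca$x), rbind(c(0, 1), c(1, 0), c(1, 0)))
  # already-canonical input is a fixed point
  expect_equal(canonicalize(ca, q)$x, ca$x)
})

test_that("random degenerate optima canonicalize to a unique form", {
  set.seed(9)
  for (i in 1:10) {
    K <- 6
    r <- sort(round(runif(K, 0.01, 0.05), 2))   # rounded -> frequent ties
    q <- risk_quantiles(r)
    pr <- build_problem(q, regimen_set(c(1, 3, 6)), nh_params(),
                        baseline_label = "3y")
    sol <- solve_lp(pr)
    ca1 <- canonicalize(sol, q)
    # shuffle rows within tied-risk groups: an equally optimal assignment
    # that must canonicalize to the identical form
    shuf <- function(v) if (length(v) == 1L) v else sample(v)
    perm <- unname(unlist(lapply(split(seq_len(K), r), shuf)))
    x2 <- sol$x[perm, , drop = FALSE]
    expect_equal(sum(x2 * pr$p), sol$objective, tolerance = 1e-12)
    ca2 <- canonicalize(screenopt:::new_assignment(
      x2, sum(x2 * pr$p), "lp", "optimal", pr, sum(x2 * pr$h)), q)
    expect_equal(ca1$x, ca2$x, tolerance = 1e-9)
    expect_equal(ca1$objective, sol$objective, tolerance = 1e-9)
  }
})

test_that("optimal solutions are scale-invariant in the risk level", {
  set.seed(31)
  for (i in 1:6) {
    K <- sample(4:8, 1)
    r <- sort(runif(K, 0.005, 0.08))
    regs <- regimen_set(c(1, 3, 6))
    base <- canonicalize(solve_lp(build_problem(
      risk_quantiles(r), regs, nh_params(), baseline_label = "3y")))
    for (M in c(0.5, 1, 2)) {
      sc <- canonicalize(solve_lp(build_problem(
        risk_quantiles(pmin(1, M * r)), regs, nh_params(),
        baseline_label = "3y")))
      expect_equal(sc$x, base$x, tolerance = 1e-9)
      expect_equal(sc$objective, M * base$objective, tolerance = 1e-9)
    }
  }
})

test_that("optimal objective never worsens with more budget", {
  set.seed(61)
  q <- risk_quantiles(sort(runif(10, 0.005, 0.08)))
  pr <- build_problem(q, regimen_set(c(1, 2, 3, 6)), nh_params(),
                      baseline_label = "3y")
  H0 <- pr$budget
  objs <- vapply(seq(0.5, 3, by = 0.1), function(cmul) {
    pr$budget <- cmul * H0
    sol <- solve_lp(pr)
    if (sol$status == "optimal") sol$objective else NA_real_
  }, numeric(1))
  objs <- objs[!is.na(objs)]
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("canonical optima give more intensive regimens to higher risk and stay nearly integral", {
  set.seed(71)
  for (i in 1:8) {
    pr <- random_instance(sample(5:8, 1), 3, separable = TRUE)
    sol <- solve_lp(pr)
    if (sol$status != "optimal") next
    ca <- canonicalize(sol)
    expect_feasible(ca, pr)
    # per-quantile expected cost non-decreasing in risk (risks are sorted)
    qcost <- rowSums(ca$x * pr$h)
    expect_true(all(diff(qcost) >= -1e-9))
    # basic-optimum structure: at most m - 1 fractional rows
    frac <- apply(ca$x, 1, function(z) any(z > 1e-7 & z < 1 - 1e-7))
    expect_lte(sum(frac), ncol(pr$p) - 1)
  }
})

test_that("problems and assignments serialize to JSON and tidy CSV", {
  q <- risk_quantiles(c(0.01, 0.02, 0.05))
  pr <- build_problem(q, regimen_set(c(1, 3)), nh_params(),
                      baseline_label = "3y")
  sol <- solve_lp(pr)
  fp <- tempfile(fileext = ".json"); fa <- tempfile(fileext = ".json")
  fc <- tempfile(fileext = ".csv")
  write_problem_json(pr, fp)
  write_assignment_json(sol, fa)
  write_assignment_csv(sol, fc)
  pj <- jsonlite::read_json(fp, simplifyVector = TRUE)
  expect_equal(pj$budget, pr$budget)
  expect_equal(unname(as.matrix(pj$p)), unname(pr$p), tolerance = 1e-12)
  aj <- jsonlite::read_json(fa, simplifyVector = TRUE)
  expect_equal(aj$objective, sol$objective, tolerance = 1e-12)
  df <- read.csv(fc)
  expect_equal(names(df), c("k", "regimen_label", "x"))
  expect_equal(sum(df$x), 3, tolerance = 1e-9)   # rows sum to one each
  unlink(c(fp, fa, fc))
})
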