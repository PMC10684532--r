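#' Assemble the screening-allocation problem
#'
#' Builds the K x m matrix of advanced-cancer risks `p_kj` (quantile k under
#' regimen j), the per-regimen costs, and the budget. Cost is screens per
#' person over the planning horizon and by default does not depend on the
#' quantile; a K x m cost matrix may be supplied for stratified extensions.
#'
#' With the triennial regimen as baseline and K = 100 centiles the
#' triennial-equivalent budget is `K * 2 = 200` screens, reproducing a
#' programme that screens everyone every 3 years over a 6-year horizon.
#'
#' @param quantiles A [risk_quantiles()] object (K strata, mean risks `r_k`).
#' @param regimens A list of [regimen()] objects (see [regimen_set()]).
#' @param params An [nh_params()] object; per-quantile parameter overrides can
#'   be expressed by passing a pre-computed `p` via `p_matrix`.
#' @param budget Total permitted cost H (screens). Exactly one of `budget` or
#'   `baseline_label` must be given; with `baseline_label`, the budget is the
#'   cost of giving that regimen to everyone (`K * h_baseline`).
#' @param baseline_label Label of the regimen whose everyone-gets-it cost
#'   defines the budget.
#' @param costs Optional override: length-m vector `h_j` or K x m matrix
#'   `h_kj`; defaults to each regimen's `cost`.
#' @param p_matrix Optional pre-computed K x m advanced-risk matrix,
#'   overriding the natural-history computation (used by sensitivity
#'   scenarios).
#' @return An object of class `screening_problem` with elements `p`, `h`
#'   (both K x m), `costs` (as supplied), `budget`, `labels`, `K`, `m`,
#'   `quantiles`, `regimens`, `params`.
#' @examples
#' q <- risk_quantiles(c(0.005, 0.01, 0.02, 0.05))
#' build_problem(q, regimen_set(c(1, 3, 4)), nh_params(), baseline_label = "3y")
#' @export
build_problem <- function(quantiles, regimens, params,
                          budget = NULL, baseline_label = NULL,
                          costs = NULL, p_matrix = NULL) {
  stopifnot(inherits(quantiles, "risk_quantiles"))
  if (length(regimens) == 0L)
    stop("`regimens` must be a non-empty list", call. = FALSE)
  stopifnot(all(vapply(regimens, inherits, logical(1), "regimen")))
  K <- quantiles$K
  m <- length(regimens)
  labels <- vapply(regimens, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("regimen labels must be unique", call. = FALSE)
  if (is.null(costs)) costs <- vapply(regimens, `[[`, numeric(1), "cost")
  if (is.matrix(costs)) {
    if (!identical(dim(costs), c(K, m)))
      stop("cost matrix must be K x m", call. = FALSE)
    h <- costs
  } else {
    if (length(costs) != m)
      stop("`costs` must have one entry per regimen", call. = FALSE)
    h <- matrix(costs, K, m, byrow = TRUE)
  }
  if (any(h <= 0)) stop("costs must be > 0", call. = FALSE)
  if (is.null(p_matrix)) {
    stopifnot(inherits(params, "nh_params"))
    p <- vapply(regimens,
                function(rg) advanced_risk(quantiles$mean_risk, params, rg),
                numeric(K))
    p <- matrix(p, K, m)
  } else {
    p <- p_matrix
    if (!identical(dim(p), c(K, m)))
      stop("`p_matrix` must be K x m", call. = FALSE)
  }
  if (any(p < 0)) stop("advanced risks must be >= 0", call. = FALSE)
  if (is.null(budget)) {
    if (is.null(baseline_label))
      stop("give either `budget` or `baseline_label`", call. = FALSE)
    jb <- match(baseline_label, labels)
    if (is.na(jb))
      stop(sprintf("baseline regimen '%s' is not among the regimens",
                   baseline_label), call. = FALSE)
    budget <- sum(h[, jb])
  }
  if (!is.numeric(budget) || budget <= 0)
    stop("`budget` must be > 0", call. = FALSE)
  colnames(p) <- colnames(h) <- labels
  structure(list(p = p, h = h, costs = costs, budget = budget,
                 labels = labels, K = K, m = m,
                 quantiles = quantiles, regimens = regimens, params = params),
            class = "screening_problem")
}

#' @export
print.screening_problem <- function(x, ...) {
  cat(sprintf("Screening allocation problem: K = %d quantiles, m = %d regimens (%s)\n",
              x$K, x$m, paste(x$labels, collapse = ", ")))
  cat(sprintf("  budget H = %.4g screens; all-j costs: %s\n", x$budget,
              paste(sprintf("%s=%.4g", x$labels, colSums(x$h)), collapse = ", ")))
  invisible(x)
}

new_assignment <- function(x, objective, mode, status, problem,
                           cost = NA_real_) {
  structure(list(x = x, objective = objective, mode = mode, status = status,
                 cost = cost, problem = problem),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("%s assignment: status %s", toupper(x$mode), x$status))
  if (x$status == "optimal")
    cat(sprintf(", objective %.6g, cost %.4g / budget %.4g",
                x$objective, x$cost, x$problem$budget))
  cat("\n")
  if (x$status == "optimal") {
    sh <- round(100 * colSums(x$x) / nrow(x$x), 1)
    cat("  population shares (%):",
        paste(sprintf("%s=%g", colnames(x$x), sh), collapse = ", "), "\n")
  }
  invisible(x)
}

# Exact LP solve by parametric Lagrangian search.
#
# min sum(x * p)  s.t.  rowSums(x) = 1,  sum(x * h) <= H,  0 <= x <= 1.
# For multiplier theta >= 0 each row independently minimizes p + theta * h.
# The minimal-cost such choice has total cost non-increasing in theta; the
# optimum sits at theta = 0 (budget slack) or at the breakpoint where the
# budget becomes attainable, with at most one row mixed between its two tied
# regimens to spend the budget exactly (complementary slackness).
lp_core <- function(p, h, H, tol = 1e-9) {
  K <- nrow(p); m <- ncol(p)
  if (m == 1L) {
    if (sum(h) > H + tol * (1 + abs(H)))
      return(list(status = "infeasible"))
    x <- matrix(1, K, 1)
    return(list(status = "optimal", x = x, objective = sum(p), cost = sum(h),
                theta = 0))
  }
  if (sum(apply(h, 1, min)) > H + tol * (1 + abs(H)))
    return(list(status = "infeasible"))

  pick <- function(theta, side) {
    v <- p + theta * h
    vmin <- do.call(pmin, as.data.frame(v))
    tie <- v <= vmin + 1e-9 * (1 + abs(vmin))
    vapply(seq_len(K), function(k) {
      js <- which(tie[k, ])
      hk <- h[k, js]
      cand <- if (side == "cheap") js[hk == min(hk)] else js[hk == max(hk)]
      if (length(cand) > 1L) cand <- cand[which.min(p[k, cand])]
      cand
    }, integer(1))
  }
  cost_of <- function(idx) sum(h[cbind(seq_len(K), idx)])
  obj_of <- function(idx) sum(p[cbind(seq_len(K), idx)])

  # breakpoints where some row's argmin of p + theta*h switches regimen
  thetas <- 0
  for (k in seq_len(K)) {
    for (j1 in seq_len(m - 1L)) for (j2 in seq((j1 + 1L), m)) {
      dh <- h[k, j1] - h[k, j2]
      if (abs(dh) > 0) {
        th <- (p[k, j2] - p[k, j1]) / dh
        if (is.finite(th) && th > 0) thetas <- c(thetas, th)
      }
    }
  }
  thetas <- sort(unique(thetas))
  thetas <- c(thetas, thetas[length(thetas)] + 1)   # beyond-last sentinel

  # smallest candidate theta whose cheap-side choice is affordable
  lo <- 1L; hi <- length(thetas)
  if (cost_of(pick(thetas[hi], "cheap")) > H + tol * (1 + abs(H)))
    return(list(status = "infeasible"))
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (cost_of(pick(thetas[mid], "cheap")) <= H + tol * (1 + abs(H)))
      hi <- mid else lo <- mid + 1L
  }
  theta <- thetas[lo]
  cheap <- pick(theta, "cheap")
  c_lo <- cost_of(cheap)
  x <- matrix(0, K, m)
  x[cbind(seq_len(K), cheap)] <- 1
  if (theta > 0 && c_lo < H - tol * (1 + abs(H))) {
    # spend remaining budget along the tie at theta: move rows from their
    # cheap to their expensive tied regimen, splitting the last row
    expensive <- pick(theta, "expensive")
    slack <- H - c_lo
    for (k in which(expensive != cheap)) {
      if (slack <= tol) break
      dk <- h[k, expensive[k]] - h[k, cheap[k]]
      f <- min(1, slack / dk)
      x[k, cheap[k]] <- 1 - f
      x[k, expensive[k]] <- f
      slack <- slack - f * dk
    }
  }
  list(status = "optimal", x = x, objective = sum(x * p), cost = sum(x * h),
       theta = theta)
}

#' Solve the population linear programme
#'
#' Minimizes expected advanced-cancer incidence `P(X) = sum_kj x_kj p_kj`
#' over fractional assignments `0 <= x_kj <= 1` with one regimen-mixture per
#' quantile (`sum_j x_kj = 1`) and a resource constraint
#' `sum_kj h_kj x_kj <= H`. Solved exactly by a parametric Lagrangian
#' method exploiting the single coupling constraint; feasibility tolerance
#' 1e-9.
#'
#' An LP optimum mixes regimens in at most one quantile per active tie, which
#' is how thresholds fall part way through a risk quantile.
#'
#' @param problem A [build_problem()] object.
#' @return An `assignment` object: `x` (K x m), `objective`, `cost`,
#'   `mode = "lp"`, `status` `"optimal"` or `"infeasible"` (infeasible
#'   budgets return the typed status rather than an error, so sweeps can skip
#'   gracefully).
#' @examples
#' q <- risk_quantiles(c(0.001, 0.01, 0.05))
#' pr <- build_problem(q, regimen_set(c(1, 3, 6)), nh_params(),
#'                     baseline_label = "3y")
#' solve_lp(pr)
#' @export
solve_lp <- function(problem) {
  stopifnot(inherits(problem, "screening_problem"))
  res <- lp_core(problem$p, problem$h, problem$budget)
  if (res$status != "optimal")
    return(new_assignment(NULL, NA_real_, "lp", res$status, problem))
  colnames(res$x) <- problem$labels
  new_assignment(res$x, res$objective, "lp", "optimal", problem, res$cost)
}

#' Solve the cohort integer programme
#'
#' Same objective and constraints as [solve_lp()] but with binary `x_kj`
#' (each quantile — or individual, for a cohort with K = n — is assigned a
#' single regimen). Solved by exhaustive enumeration when `m^K` is small
#' (<= `enum_limit`) and otherwise by LP-based branch-and-bound, branching on
#' the fractional row of the relaxation; both are exact. The IP objective is
#' always >= the LP objective.
#'
#' @param problem A [build_problem()] object.
#' @param enum_limit Maximum `m^K` for plain enumeration (default 2e4).
#' @return An `assignment` with `mode = "ip"`.
#' @export
solve_ip <- function(problem, enum_limit = 2e4) {
  stopifnot(inherits(problem, "screening_problem"))
  p <- problem$p; h <- problem$h; H <- problem$budget
  K <- problem$K; m <- problem$m
  tolH <- 1e-9 * (1 + abs(H))
  if (sum(apply(h, 1, min)) > H + tolH)
    return(new_assignment(NULL, NA_real_, "ip", "infeasible", problem))
  if (m^K <= enum_limit) {
    enum <- enumerate_integer(p, h)
    feas <- enum$cost <= H + tolH
    best <- which(feas)[which.min(enum$obj[feas])]
    idx <- enum$A[best, ]
  } else {
    idx <- ip_branch_bound(p, h, H)
  }
  x <- matrix(0, K, m, dimnames = list(NULL, problem$labels))
  x[cbind(seq_len(K), idx)] <- 1
  new_assignment(x, sum(x * p), "ip", "optimal", problem, sum(x * h))
}

# all m^K integer assignments with their objectives and costs
enumerate_integer <- function(p, h) {
  K <- nrow(p); m <- ncol(p)
  A <- as.matrix(expand.grid(rep(list(seq_len(m)), K)))
  dimnames(A) <- NULL
  N <- nrow(A)
  rows <- matrix(rep(seq_len(K), each = N), N, K)
  lin <- as.vector((A - 1L) * K + rows)   # as.vector: avoid coordinate-pair
  list(A = A, obj = rowSums(matrix(p[lin], N, K)),      # indexing when K == 2
       cost = rowSums(matrix(h[lin], N, K)))
}

# depth-first branch and bound on the LP relaxation's fractional row
ip_branch_bound <- function(p, h, H) {
  K <- nrow(p)
  best_obj <- Inf
  best_idx <- NULL
  rec <- function(fixed, free, acc_obj, acc_cost) {
    rem_H <- H - acc_cost
    if (length(free) == 0L) {
      if (acc_cost <= H + 1e-9 * (1 + abs(H)) && acc_obj < best_obj) {
        best_obj <<- acc_obj; best_idx <<- fixed
      }
      return(invisible())
    }
    lp <- lp_core(p[free, , drop = FALSE], h[free, , drop = FALSE], rem_H)
    if (lp$status != "optimal") return(invisible())
    if (acc_obj + lp$objective >= best_obj - 1e-12) return(invisible())
    frac_rows <- which(apply(lp$x, 1, function(r) any(r > 1e-9 & r < 1 - 1e-9)))
    if (length(frac_rows) == 0L) {
      idx <- apply(lp$x, 1, which.max)
      cand <- acc_obj + lp$objective
      if (cand < best_obj) {
        best_obj <<- cand
        full <- integer(K); full[names(fixed) |> as.integer()] <- fixed
        full[free] <- idx
        best_idx <<- full
      }
      return(invisible())
    }
    k <- free[frac_rows[1]]
    for (j in order(p[k, ])) {
      nf <- fixed; nf[as.character(k)] <- j
      rec(nf, setdiff(free, k), acc_obj + p[k, j], acc_cost + h[k, j])
    }
    invisible()
  }
  rec(stats::setNames(integer(0), character(0)), seq_len(K), 0, 0)
  # translate the named 'fixed' vector captured at the leaf into row order
  if (is.null(best_idx)) stop("branch and bound found no solution",
                              call. = FALSE)
  if (!is.null(names(best_idx)) && any(names(best_idx) != "")) {
    full <- integer(K)
    full[as.integer(names(best_idx))] <- best_idx
    best_idx <- full
  }
  best_idx
}

#' Exhaustive verification oracle
#'
#' Independent brute-force search over assignments, for verifying the
#' optimizers on tiny instances (refuses `K > 8` or `m > 3`). `mode = "ip"`
#' enumerates all `m^K` binary assignments. `mode = "lp"` additionally grids,
#' for every binary base assignment, every single-row mixture of two regimens
#' in steps of `grid_step` — the family that contains every vertex of the
#' feasible polytope (K equality constraints plus one budget constraint leave
#' at most one fractional row), so the LP optimum is approached within grid
#' resolution.
#'
#' @param problem A [build_problem()] object with `K <= 8`, `m <= 3`.
#' @param grid_step Mixing-fraction grid step for `mode = "lp"`.
#' @param mode `"lp"` or `"ip"`.
#' @return An `assignment` object (the best feasible grid point).
#' @export
brute_force <- function(problem, grid_step = 0.01, mode = c("lp", "ip")) {
  stopifnot(inherits(problem, "screening_problem"))
  mode <- match.arg(mode)
  if (problem$K > 8 || problem$m > 3)
    stop("brute_force refuses instances larger than K = 8, m = 3",
         call. = FALSE)
  p <- problem$p; h <- problem$h; H <- problem$budget
  K <- problem$K; m <- problem$m
  tolH <- 1e-9 * (1 + abs(H))
  enum <- enumerate_integer(p, h)
  feas <- enum$cost <= H + tolH
  if (!any(feas))
    return(new_assignment(NULL, NA_real_, mode, "infeasible", problem))
  bi <- which(feas)[which.min(enum$obj[feas])]
  best <- list(obj = enum$obj[bi], base = enum$A[bi, ], k = NA, j = NA, t = 0)
  if (mode == "lp") {
    tgrid <- seq(0, 1, by = grid_step)
    N <- nrow(enum$A)
    for (k in seq_len(K)) {
      jc <- enum$A[, k]                       # current regimen of row k
      for (j in seq_len(m)) {
        dp <- p[k, j] - p[k, jc]              # per-combo objective delta
        dh <- h[k, j] - h[k, jc]
        for (t in tgrid) {
          o <- enum$obj + t * dp
          cst <- enum$cost + t * dh
          ok <- cst <= H + tolH & o < best$obj
          if (any(ok)) {
            i <- which(ok)[which.min(o[ok])]
            best <- list(obj = o[i], base = enum$A[i, ], k = k, j = j, t = t)
          }
        }
      }
    }
  }
  x <- matrix(0, K, m, dimnames = list(NULL, problem$labels))
  x[cbind(seq_len(K), best$base)] <- 1
  if (!is.na(best$k) && best$t > 0) {
    jc <- best$base[best$k]
    x[best$k, jc] <- x[best$k, jc] - best$t
    x[best$k, best$j] <- x[best$k, best$j] + best$t
  }
  new_assignment(x, sum(x * p), mode, "optimal", problem, sum(x * h))
}

#' Canonical tie-broken form of an optimal assignment
#'
#' Degenerate instances (ties in risk or in the Lagrangian) admit many
#' optimal assignments. This returns the unique canonical representative:
#' quantiles sorted by descending risk receive regimen mass in order of
#' descending cost, so regimen intensity is non-increasing in risk rank and
#' groups are contiguous. Because `p_kj = r_k c_j` separates stratum risk
#' from regimen effectiveness, the rearrangement never worsens the objective;
#' it is verified unchanged (1e-8 relative) and the input is returned with a
#' warning in the non-separable case where it would differ.
#'
#' @param assignment An optimal `assignment`.
#' @param quantiles The [risk_quantiles()] the problem was built from;
#'   defaults to the ones stored in the assignment's problem.
#' @return An `assignment` with the same objective and mode.
#' @export
canonicalize <- function(assignment, quantiles = assignment$problem$quantiles) {
  stopifnot(inherits(assignment, "assignment"))
  if (assignment$status != "optimal") return(assignment)
  x <- assignment$x
  problem <- assignment$problem
  K <- nrow(x); m <- ncol(x)
  hbar <- colMeans(problem$h)
  # highest risk first; regimen queue most expensive first
  krank <- order(quantiles$mean_risk, seq_len(K), decreasing = TRUE)
  jrank <- order(hbar, colnames(x), decreasing = TRUE)
  mass <- colSums(x)[jrank]
  xc <- matrix(0, K, m, dimnames = dimnames(x))
  g <- 1L
  for (k in krank) {
    need <- 1
    while (need > 1e-12 && g <= m) {
      take <- min(need, mass[g])
      xc[k, jrank[g]] <- xc[k, jrank[g]] + take
      mass[g] <- mass[g] - take
      need <- need - take
      if (mass[g] <= 1e-12) g <- g + 1L
    }
  }
  obj <- sum(xc * problem$p)
  cost <- sum(xc * problem$h)
  tol <- 1e-8 * (1 + abs(assignment$objective))
  if (obj > assignment$objective + tol ||
      cost > problem$budget + 1e-9 * (1 + abs(problem$budget))) {
    warning("canonical rearrangement would change the objective or break ",
            "the budget (non-separable risks?); returning input unchanged",
            call. = FALSE)
    return(assignment)
  }
  new_assignment(xc, obj, assignment$mode, "optimal", problem, cost)
}

#' Serialize problems and assignments
#'
#' `write_problem_json()`/`write_assignment_json()` store matrices row-major
#' with regimen labels; `write_assignment_csv()` writes the tidy summary
#' `k,regimen_label,x` (one row per nonzero cell).
#'
#' @param problem A `screening_problem`.
#' @param assignment An `assignment`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_problem_json <- function(problem, path) {
  stopifnot(inherits(problem, "screening_problem"))
  obj <- list(K = problem$K, m = problem$m, labels = problem$labels,
              budget = problem$budget,
              p = apply(problem$p, 1, identity, simplify = FALSE),
              costs = if (is.matrix(problem$costs))
                apply(problem$costs, 1, identity, simplify = FALSE)
              else problem$costs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_problem_json
#' @export
write_assignment_json <- function(assignment, path) {
  stopifnot(inherits(assignment, "assignment"))
  obj <- list(mode = assignment$mode, status = assignment$status,
              objective = assignment$objective, cost = assignment$cost,
              labels = colnames(assignment$x),
              x = if (is.null(assignment$x)) NULL
                  else apply(assignment$x, 1, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_problem_json
#' @export
write_assignment_csv <- function(assignment, path) {
  stopifnot(inherits(assignment, "assignment"),
            assignment$status == "optimal")
  x <- assignment$x
  idx <- which(x > 1e-12, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(k = idx[, 1], regimen_label = colnames(x)[idx[, 2]],
                   x = x[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
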