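#' Population risk distribution in equal-count quantiles
#'
#' Holds the per-quantile mean invasive-cancer risk `r_k` for `K` quantiles of
#' equal population weight `1/K`, together with the `K + 1` risk-score cut
#' points that delimit the quantiles on the original score scale.
#'
#' @param mean_risk Numeric vector of per-quantile mean risks, ordered by
#'   quantile index (non-decreasing), all in \[0, 1\].
#' @param boundaries Optional numeric vector of length `K + 1` of
#'   non-decreasing score cut points. When absent, score-scale threshold
#'   extraction is unavailable but the optimization itself is unaffected.
#' @return An object of class `risk_quantiles` with elements `K`, `mean_risk`,
#'   `weight`, `boundaries`.
#' @examples
#' risk_quantiles(c(0.005, 0.01, 0.02, 0.05))
#' @export
risk_quantiles <- function(mean_risk, boundaries = NULL) {
  stopifnot(is.numeric(mean_risk), length(mean_risk) >= 1L)
  if (any(!is.finite(mean_risk)) || any(mean_risk < 0) || any(mean_risk > 1))
    stop("`mean_risk` values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(mean_risk))
    stop("`mean_risk` must be non-decreasing in quantile index", call. = FALSE)
  K <- length(mean_risk)
  if (!is.null(boundaries)) {
    stopifnot(is.numeric(boundaries))
    if (length(boundaries) != K + 1L)
      stop("`boundaries` must have length K + 1", call. = FALSE)
    if (is.unsorted(boundaries))
      stop("`boundaries` must be non-decreasing", call. = FALSE)
  }
  structure(list(K = K, mean_risk = as.numeric(mean_risk), weight = 1 / K,
                 boundaries = if (is.null(boundaries)) NULL
                              else as.numeric(boundaries)),
            class = "risk_quantiles")
}

#' @export
print.risk_quantiles <- function(x, ...) {
  cat(sprintf("Risk distribution in %d equal-count quantiles\n", x$K))
  cat(sprintf("  mean risk: %.4g (lowest) .. %.4g (highest); population mean %.4g\n",
              x$mean_risk[1], x$mean_risk[x$K], mean(x$mean_risk)))
  if (!is.null(x$boundaries))
    cat(sprintf("  score range: [%.4g, %.4g]\n",
                x$boundaries[1], x$boundaries[x$K + 1]))
  invisible(x)
}

#' Build risk quantiles from individual risk scores
#'
#' Splits an empirical risk-score distribution into `K` equal-count quantiles
#' and records the mean score in each as that quantile's invasive risk. By
#' default only controls define the population distribution (case-control
#' designs over-represent cases); set `use_controls_only = FALSE` for cohort
#' samples.
#'
#' The `i`-th internal cut point is the order statistic of rank
#' `ceiling(i * n / K)` (1-based), and quantile `k` contains the ranks in
#' `(ceiling((k-1) n / K), ceiling(k n / K)]`; ties spanning a cut point are
#' assigned to the lower quantile by rank, deterministically. The outer
#' boundaries are the sample minimum and maximum.
#'
#' @param sample A score sample: a data.frame with columns `status`
#'   (`"case"`/`"control"`) and `risk`, as produced by
#'   [synthesize_case_control()] or [read_scores()]; or a bare numeric vector
#'   of scores (then `use_controls_only` is ignored).
#' @param K Number of quantiles (>= 2); 100 (centiles) in the intended
#'   application.
#' @param use_controls_only Use only `status == "control"` records.
#' @return A [risk_quantiles()] object.
#' @examples
#' s <- synthesize_case_control(200, 200, seed = 1)
#' quantiles_from_scores(s, K = 10)
#' @export
quantiles_from_scores <- function(sample, K = 100, use_controls_only = TRUE) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 2)
  K <- as.integer(K)
  if (is.numeric(sample)) {
    scores <- sample
  } else {
    stopifnot(is.data.frame(sample),
              all(c("status", "risk") %in% names(sample)))
    scores <- if (use_controls_only)
      sample$risk[sample$status == "control"] else sample$risk
    if (use_controls_only && length(scores) == 0L)
      stop("no control records to build the population distribution",
           call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("risk scores must lie in [0, 1]", call. = FALSE)
  n <- length(scores)
  if (n < K)
    stop(sprintf("need at least K = %d usable records, got %d", K, n),
         call. = FALSE)
  s <- sort(scores)
  hi <- ceiling(seq_len(K) * n / K)            # upper rank of each quantile
  lo <- c(0L, hi[-K]) + 1L
  mean_risk <- vapply(seq_len(K), function(k) mean(s[lo[k]:hi[k]]), numeric(1))
  boundaries <- c(s[1], s[hi])
  risk_quantiles(mean_risk, boundaries)
}

#' Map an optimized assignment back to risk-score thresholds
#'
#' Converts a (canonical, contiguous) quantile-to-regimen assignment into
#' population shares and risk-score group boundaries. Fractional assignment
#' within a quantile places the threshold part way through that quantile,
#' interpolated linearly in rank between the quantile's boundary scores.
#'
#' @param quantiles A [risk_quantiles()] object with score `boundaries`.
#' @param assignment An [solve_lp()]/[solve_ip()] `assignment` (rows must sum
#'   to 1). Pass through [canonicalize()] first if it may contain
#'   non-contiguous optima.
#' @return A data.frame of class `group_thresholds` with one row per regimen
#'   that receives population mass: `label`, `share_pct`, `lower_score`,
#'   `upper_score`. If the assignment is not contiguous in quantile order a
#'   warning is raised and the score bounds are `NA` (shares still reported).
#' @export
thresholds_from_assignment <- function(quantiles, assignment) {
  stopifnot(inherits(quantiles, "risk_quantiles"),
            inherits(assignment, "assignment"))
  x <- assignment$x
  K <- nrow(x)
  if (K != quantiles$K)
    stop("assignment and quantiles disagree on K", call. = FALSE)
  if (max(abs(rowSums(x) - 1)) > 1e-6)
    stop("assignment rows must sum to 1", call. = FALSE)
  labels <- colnames(x)
  share <- colSums(x) / K * 100
  keep <- share > 1e-9
  # order regimen groups by their average position along the risk-sorted axis
  pos <- vapply(seq_along(labels), function(j) {
    if (!keep[j]) return(NA_real_)
    sum(x[, j] * seq_len(K)) / sum(x[, j])
  }, numeric(1))
  ord <- order(pos, na.last = NA)
  cuts <- cumsum(colSums(x)[ord])              # cumulative mass, quantile units
  starts <- c(0, cuts[-length(cuts)])
  # reconstruct the contiguous assignment implied by the cut points and
  # compare; mismatch means the optimum interleaves regimens along risk
  xe <- matrix(0, K, ncol(x))
  for (g in seq_along(ord)) {
    j <- ord[g]
    xe[, j] <- pmax(0, pmin(seq_len(K), cuts[g]) - pmin(seq_len(K) - 1, cuts[g])
                    - pmax(0, pmin(seq_len(K), starts[g])
                           - pmin(seq_len(K) - 1, starts[g])))
  }
  contiguous <- max(abs(xe - x)) <= 1e-6
  b <- quantiles$boundaries
  score_at <- function(c) {
    if (is.null(b)) return(NA_real_)
    c <- max(0, min(K, c))
    q <- min(floor(c), K - 1) + 1
    f <- c - (q - 1)
    b[q] + f * (b[q + 1] - b[q])
  }
  if (!contiguous) {
    warning("assignment is not contiguous in risk order; ",
            "score bounds omitted (shares still reported)", call. = FALSE)
    out <- data.frame(label = labels[keep], share_pct = share[keep],
                      lower_score = NA_real_, upper_score = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(label = labels[ord],
                      share_pct = share[ord],
                      lower_score = vapply(starts, score_at, numeric(1)),
                      upper_score = vapply(cuts, score_at, numeric(1)),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("group_thresholds", "data.frame")
  out
}

#' Generate a synthetic case-control risk-score sample
#'
#' Emulates the kind of case-control risk-score data produced when an AI risk
#' model is evaluated against screening outcomes: control scores follow a
#' log-normal law truncated to \[0, 1\], and case scores follow the
#' risk-proportional tilt of that law (density proportional to `r f(r)`), so
#' cases are enriched at high risk. The tilt is sampled exactly via the
#' log-normal identity `r * dlnorm(r; mu, sigma)` proportional to
#' `dlnorm(r; mu + sigma^2, sigma)`.
#'
#' Default `mu`/`sigma` place 32% of controls below a 3-year risk of about
#' 1.56% and 4% above about 5.06%, matching the degree of stratification an
#' imaging AI model achieves in mammography screening.
#'
#' @param n_cases,n_controls Record counts (> 0).
#' @param mu Location of log risk among controls.
#' @param sigma Scale of log risk (> 0); larger values give stronger
#'   case/control discrimination.
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @return A data.frame of class `score_sample` with columns `id`, `status`
#'   (`"case"` or `"control"`), `risk`.
#' @examples
#' s <- synthesize_case_control(500, 500, seed = 42)
#' tapply(s$risk, s$status, mean)   # cases exceed controls
#' @export
synthesize_case_control <- function(n_cases = 2044, n_controls = 2044,
                                    mu = -3.912, sigma = 0.530, seed = NULL) {
  stopifnot(is.numeric(n_cases), n_cases >= 1,
            is.numeric(n_controls), n_controls >= 1,
            is.numeric(sigma), sigma > 0)
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (!is.null(seed)) set.seed(as.integer(seed))
  trunc_mass <- max(stats::plnorm(1, mu, sigma, lower.tail = FALSE),
                    stats::plnorm(1, mu + sigma^2, sigma, lower.tail = FALSE))
  if (trunc_mass > 0.05)
    warning(sprintf("truncation at risk 1 removes %.1f%% of the mass; ",
                    100 * trunc_mass),
            "scores will pile up below 1", call. = FALSE)
  draw_trunc <- function(n, m) {
    r <- stats::rlnorm(n, m, sigma)
    while (any(bad <- r > 1)) r[bad] <- stats::rlnorm(sum(bad), m, sigma)
    r
  }
  controls <- draw_trunc(n_controls, mu)
  cases <- draw_trunc(n_cases, mu + sigma^2)   # exponential tilt by r
  out <- data.frame(
    id = sprintf("s%06d", seq_len(n_cases + n_controls)),
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    risk = c(cases, controls),
    stringsAsFactors = FALSE)
  class(out) <- c("score_sample", "data.frame")
  out
}

#' Read / write score samples and quantiles as CSV
#'
#' `read_scores()` expects the header `id,status,risk` with
#' `status` in `{case, control}`; `write_scores()` writes the same layout.
#' `write_quantiles()`/`read_quantiles()` round-trip a [risk_quantiles()]
#' object through the header `k,mean_risk,lower_bound,upper_bound`.
#'
#' @param path File path.
#' @param sample A `score_sample` data.frame.
#' @param quantiles A [risk_quantiles()] object.
#' @return The read object, or (for writers) the path invisibly.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "status", "risk")
  if (!all(need %in% names(df)))
    stop("score CSV must have columns id,status,risk", call. = FALSE)
  if (!all(df$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'", call. = FALSE)
  if (any(!is.finite(df$risk)) || any(df$risk < 0) || any(df$risk > 1))
    stop("risk must lie in [0, 1]", call. = FALSE)
  class(df) <- c("score_sample", "data.frame")
  df
}

#' @rdname read_scores
#' @export
write_scores <- function(sample, path) {
  utils::write.csv(as.data.frame(sample)[, c("id", "status", "risk")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_scores
#' @export
write_quantiles <- function(quantiles, path) {
  stopifnot(inherits(quantiles, "risk_quantiles"))
  K <- quantiles$K
  b <- quantiles$boundaries
  df <- data.frame(k = seq_len(K), mean_risk = quantiles$mean_risk,
                   lower_bound = if (is.null(b)) NA_real_ else b[seq_len(K)],
                   upper_bound = if (is.null(b)) NA_real_ else b[seq_len(K) + 1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_scores
#' @export
read_quantiles <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("k", "mean_risk") %in% names(df)))
    stop("quantile CSV must have columns k,mean_risk[,lower_bound,upper_bound]",
         call. = FALSE)
  df <- df[order(df$k), ]
  b <- NULL
  if (all(c("lower_bound", "upper_bound") %in% names(df)) &&
      !anyNA(df$lower_bound) && !anyNA(df$upper_bound))
    b <- c(df$lower_bound, df$upper_bound[nrow(df)])
  risk_quantiles(df$mean_risk, b)
}
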