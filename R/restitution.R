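#' Assemble an APD restitution curve
#'
#' Pairs each analyzed cycle length's APD80 with its diastolic interval
#' (DI = CL - APD80) and orders the points by DI ascending. At least two
#' cycle lengths are required; an APD reaching its cycle length is an
#' error (no valid restitution pair exists).
#'
#' @param apd_by_cl Named numeric vector (or list) mapping cycle length
#'   (ms, as names) to APD80 (ms).
#' @return A `restitution_curve`: data frame with columns `cl`, `di`,
#'   `apd80`, sorted by `di`.
#' @export
build_restitution <- function(apd_by_cl) {
  apd <- unlist(apd_by_cl)
  cl <- as.numeric(names(apd))
  if (any(is.na(cl))) stop("apd_by_cl must be named by cycle length (ms)")
  keep <- is.finite(apd)
  cl <- cl[keep]; apd <- apd[keep]
  if (length(cl) < 2) stop(">= 2 points required for a restitution curve")
  di <- diastolic_interval(cl, apd)
  o <- order(di)
  structure(data.frame(cl = cl[o], di = di[o], apd80 = apd[o]),
            class = c("restitution_curve", "data.frame"))
}

#' Maximum local slope of a restitution curve
#'
#' Two estimators of the restitution slope (dimensionless, ms/ms):
#' `segmentwise` (default) takes the chord slope of each adjacent pair of
#' points and reports the maximum -- the slope "in each part" of the
#' curve; `exponential` fits `APD = A - B exp(-DI / tau)` by nonlinear
#' least squares and reports the maximum derivative `B/tau exp(-DI/tau)`
#' over the observed DI range (attained at the smallest DI). A
#' non-convergent exponential fit falls back to segmentwise with a
#' warning. Slopes of 1 and above are classically pro-arrhythmic.
#'
#' @param curve A [build_restitution()] curve.
#' @param method `"segmentwise"` or `"exponential"`.
#' @return Maximum local slope, with attributes `method` and (for the
#'   exponential fit) `coef`; segmentwise also attaches the per-segment
#'   slopes.
#' @export
restitution_slope <- function(curve, method = c("segmentwise", "exponential")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "restitution_curve"))
  if (any(diff(curve$di) <= 0)) stop("DI values must be strictly increasing")
  if (method == "segmentwise") {
    sl <- diff(curve$apd80) / diff(curve$di)
    return(structure(max(sl), method = "segmentwise", segments = sl))
  }
  if (nrow(curve) < 3) stop("exponential fit needs >= 3 points")
  fit <- tryCatch({
    a0 <- max(curve$apd80); b0 <- max(a0 - min(curve$apd80), 1)
    minpack.lm::nlsLM(apd80 ~ A - B * exp(-di / tau), data = curve,
                      start = list(A = a0, B = 2 * b0,
                                   tau = diff(range(curve$di)) / 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential fit did not converge; falling back to segmentwise")
    return(restitution_slope(curve, "segmentwise"))
  }
  cf <- coef(fit)
  slope <- cf["B"] / cf["tau"] * exp(-min(curve$di) / cf["tau"])
  structure(unname(slope), method = "exponential", coef = cf)
}

#' Kruskal-Wallis rank test
#'
#' Omnibus nonparametric comparison of two or more groups. The H statistic
#' (tie-corrected) and the chi-square p come from [stats::kruskal.test()];
#' for small samples (total n <= 8 under `p_method = "auto"`) the p value
#' is computed exactly by exhaustive enumeration of all assignments of the
#' pooled observations to groups, where the chi-square approximation is
#' unreliable. Identical observations across all groups give H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group (each n >= 1,
#'   total n >= 3).
#' @param p_method `"auto"`, `"chisq"` or `"exact"`.
#' @param exact_max Largest total n for which `"auto"` enumerates exactly.
#' @return List with `statistic` (H), `p.value`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("auto", "chisq", "exact"),
                           exact_max = 8) {
  p_method <- match.arg(p_method)
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (length(groups) < 2 || any(sizes < 1) || sum(sizes) < 3)
    stop("need >= 2 groups, each non-empty, total n >= 3")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1)
    return(list(statistic = 0, p.value = 1, df = length(groups) - 1,
                method = "degenerate"))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && sum(sizes) <= exact_max)
  if (!use_exact)
    return(list(statistic = H, p.value = unname(kt$p.value),
                df = unname(kt$parameter), method = "chisq"))
  if (sum(sizes) > 12)
    stop("exact enumeration is limited to total n <= 12")
  p <- .kw_exact_p(x, sizes, H)
  list(statistic = H, p.value = p, df = length(groups) - 1, method = "exact")
}

# exact permutation p: enumerate every partition of the pooled ranks into
# groups of the observed sizes and count H >= H_obs
.kw_exact_p <- function(x, sizes, H_obs) {
  r <- rank(x)
  N <- length(r)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_of <- function(split) {
    s <- vapply(split, function(i) sum(r[i]), 0)
    (12 / (N * (N + 1)) * sum(s^2 / sizes) - 3 * (N + 1)) / tie_corr
  }
  count <- 0L; ge <- 0L
  recurse <- function(remaining, gi, acc) {
    if (gi == length(sizes)) {
      split <- c(acc, list(remaining))
      count <<- count + 1L
      if (h_of(split) >= H_obs - 1e-9) ge <<- ge + 1L
      return(invisible())
    }
    ch <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (sel in ch)
      recurse(setdiff(remaining, sel), gi + 1L, c(acc, list(sel)))
  }
  recurse(seq_len(N), 1L, list())
  ge / count
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' following a significant Kruskal-Wallis omnibus test. By convention the
#' post hoc is only run when the omnibus p is below `alpha` (set
#' `gate = FALSE` to override); the gating decision is recorded in the
#' result. Both unadjusted and Holm-adjusted two-sided p values are
#' reported.
#'
#' @param groups List of numeric vectors, one per group, each n >= 1.
#' @param alpha Gate level for the omnibus test.
#' @param gate Run only when the Kruskal-Wallis p is below `alpha`?
#' @param p_method Passed to [kruskal_wallis()].
#' @return List with `z`, `p_unadjusted`, `p_holm` (symmetric matrices),
#'   `kw` (the omnibus result), `run` and `gated`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05, gate = TRUE,
                         p_method = "auto") {
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("every group must be non-empty")
  k <- length(groups)
  kw <- kruskal_wallis(groups, p_method = p_method)
  nm <- if (!is.null(names(groups))) names(groups) else paste0("g", seq_len(k))
  empty <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (gate && kw$p.value >= alpha)
    return(list(z = empty, p_unadjusted = empty, p_holm = empty,
                kw = kw, run = FALSE, gated = TRUE))

  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  idx <- rep(seq_len(k), sizes)
  rbar <- tapply(r, idx, mean)
  z <- p <- empty
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(max(N * (N + 1) / 12 - tie_term, 0) *
                 (1 / sizes[i] + 1 / sizes[j]))
    # se is zero only when every pooled observation is tied
    zij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    z[i, j] <- zij; z[j, i] <- -zij
    p[i, j] <- p[j, i] <- 2 * pnorm(-abs(zij))
  }
  up <- upper.tri(p)
  ph <- empty
  ph[up] <- p.adjust(p[up], method = "holm")
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  list(z = z, p_unadjusted = p, p_holm = ph, kw = kw,
       run = TRUE, gated = gate)
}

#' Trend of a measurement across cycle lengths
#'
#' Linear-model trend test ("p for trend"): the measurement is regressed
#' on the rank of the cycle length, with subjects as replicates, and the
#' two-sided p for the slope term is reported. Ranks follow the
#' conventional table order from the longest cycle length to the
#' shortest, so a quantity that falls as pacing accelerates (e.g. APD80)
#' has a negative trend slope.
#'
#' @param values Measurements.
#' @param cl Cycle length (ms) of each measurement.
#' @return List with `p`, `slope`, `sign` and `n_levels`. Levels with no
#'   observations are dropped with a warning; fewer than 3 remaining
#'   levels is an error.
#' @export
trend_test <- function(values, cl) {
  keep <- is.finite(values) & is.finite(cl)
  if (any(!keep)) {
    warning(sprintf("dropping %d incomplete observations", sum(!keep)))
    values <- values[keep]; cl <- cl[keep]
  }
  lev <- sort(unique(cl), decreasing = TRUE)     # table order: 400 -> 150
  if (length(lev) < 3) stop("trend test needs >= 3 cycle-length levels")
  score <- match(cl, lev)
  fit <- lm(values ~ score)
  # summary.lm warns on an exactly collinear fit; the zero-residual case is
  # handled explicitly below
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  slope <- cf["score", "Estimate"]
  # with zero residual variance the slope p is exactly 0 for a real trend
  p <- if (nrow(cf) < 2 || !is.finite(cf["score", "Pr(>|t|)"])) {
    if (abs(slope) > 0) 0 else 1
  } else cf["score", "Pr(>|t|)"]
  if (sfit$sigma < 1e-10) p <- if (abs(slope) > 1e-12) 0 else 1
  list(p = unname(p), slope = unname(slope),
       sign = sign(unname(slope)), n_levels = length(lev))
}

#' Teichholz ejection fraction
#'
#' M-mode left-ventricular ejection fraction from end-diastolic and
#' end-systolic diameters via the Teichholz volume formula
#' `V(D) = 7.0 / (2.4 + D) * D^3` (D in cm, V in mL):
#' `LVEF = 100 (V(LVEDD) - V(LVESD)) / V(LVEDD)`.
#'
#' @param lvedd,lvesd End-diastolic and end-systolic diameters; must
#'   satisfy `0 < lvesd <= lvedd`.
#' @param units `"cm"` (default) or `"mm"`.
#' @return LVEF in percent (vectorized).
#' @export
teichholz_ef <- function(lvedd, lvesd, units = c("cm", "mm")) {
  units <- match.arg(units)
  if (units == "mm") { lvedd <- lvedd / 10; lvesd <- lvesd / 10 }
  if (any(!is.finite(lvedd) | !is.finite(lvesd))) stop("diameters must be finite")
  if (any(lvesd <= 0)) stop("lvesd must be positive")
  if (any(lvesd > lvedd)) stop("lvesd must not exceed lvedd")
  V <- function(D) 7.0 / (2.4 + D) * D^3
  100 * (V(lvedd) - V(lvesd)) / V(lvedd)
}

#' Per-group summary table with omnibus, post hoc and trend statistics
#'
#' Builds the standard per-cycle-length group table: for each cycle
#' length, per-group mean, sample SD (n-1 denominator) and n, with a
#' Kruskal-Wallis omnibus p, Dunn's pairwise matrix (gated at
#' `alpha`), and a per-group trend p across cycle lengths.
#'
#' @param data Data frame with columns `subject_id`, `group`, `cl_ms` and
#'   the measurement column `value_col`.
#' @param value_col Name of the measurement column.
#' @param cls Cycle lengths to tabulate (default: all present, descending).
#' @param alpha Gate level for the post hoc.
#' @return A `group_table`: list with `summary` (data frame), `dunn`
#'   (per-CL post hoc results), `trend` (per-group), `value_col`.
#' @export
summarize_groups <- function(data, value_col, cls = NULL, alpha = 0.05) {
  need <- c("subject_id", "group", "cl_ms", value_col)
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (is.null(cls)) cls <- sort(unique(data$cl_ms), decreasing = TRUE)
  groups <- unique(as.character(data$group))

  rows <- list(); dunn <- list()
  for (cl in cls) {
    d <- data[data$cl_ms == cl & is.finite(data[[value_col]]), ]
    by_g <- lapply(groups, function(g) d[[value_col]][d$group == g])
    names(by_g) <- groups
    nz <- by_g[lengths(by_g) > 0]
    row <- list(cl_ms = cl)
    for (g in groups) {
      v <- by_g[[g]]
      row[[paste0(g, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(g, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
      row[[paste0(g, "_n")]] <- length(v)
    }
    row$p_value <- if (length(nz) >= 2 && sum(lengths(nz)) >= 3)
      kruskal_wallis(nz)$p.value else NA_real_
    rows[[as.character(cl)]] <- as.data.frame(row)
    dunn[[as.character(cl)]] <- if (is.finite(row$p_value))
      dunn_posthoc(nz, alpha = alpha) else NULL
  }

  trend <- lapply(groups, function(g) {
    d <- data[data$group == g & data$cl_ms %in% cls &
                is.finite(data[[value_col]]), ]
    if (length(unique(d$cl_ms)) < 3) return(list(p = NA_real_, slope = NA_real_))
    tr <- trend_test(d[[value_col]], d$cl_ms)
    list(p = tr$p, slope = tr$slope)
  })
  names(trend) <- groups

  structure(list(summary = do.call(rbind, rows), dunn = dunn,
                 trend = trend, value_col = value_col, groups = groups),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat(sprintf("<group_table> %s by cycle length\n", x$value_col))
  print(x$summary, row.names = FALSE, digits = 4)
  tp <- vapply(x$trend, function(t) t$p, 0)
  cat("p for trend:", paste(sprintf("%s=%.3g", names(tp), tp), collapse = "  "),
      "\n")
  invisible(x)
}
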