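test_that("restitution points are DI-sorted CL/APD pairs", {
  rc <- build_restitution(c("400" = 100, "300" = 90, "250" = 85, "200" = 70))
  expect_equal(rc$di, c(130, 165, 210, 300))
  expect_equal(rc$apd80, c(70, 85, 90, 100))
  expect_error(build_restitution(c("400" = 100)), ">= 2")
  expect_error(build_restitution(c("400" = 100, "200" = 210)), "shorter")
})

test_that("failing-heart table means give the expected diastolic intervals", {
  rc <- build_restitution(c("400" = 108.362, "300" = 93.684,
                            "250" = 84.198, "200" = 67.809))
  expect_equal(rc$di, c(132.191, 165.802, 206.316, 291.638))
})

test_that("segmentwise slope is exact on collinear and flat data", {
  di <- c(100, 150, 220, 300)
  apd <- 50 + 0.1 * di                    # cl = di + apd by definition
  rc <- build_restitution(setNames(apd, di + apd))
  expect_equal(as.numeric(restitution_slope(rc)), 0.1, tolerance = 1e-12)
  exp_sl <- restitution_slope(rc, "exponential")
  expect_equal(as.numeric(exp_sl), 0.1, tolerance = 0.05)
  flat <- build_restitution(setNames(c(80, 80), c(200 + 80, 400 + 80)))
  expect_equal(as.numeric(restitution_slope(flat)), 0)
})

test_that("exponential fit recovers its own generating parameters", {
  A <- 120; B <- 60; tau <- 90
  di <- c(60, 90, 130, 180, 250, 330)
  apd <- A - B * exp(-di / tau)
  rc <- build_restitution(setNames(apd, di + apd))
  sl <- restitution_slope(rc, "exponential")
  cf <- attr(sl, "coef")
  expect_equal(unname(cf["A"]), A, tolerance = 0.01)
  expect_equal(unname(cf["B"]), B, tolerance = 0.01)
  expect_equal(unname(cf["tau"]), tau, tolerance = 0.01)
  expect_equal(as.numeric(sl), B / tau * exp(-60 / tau), tolerance = 0.01)
})

test_that("Kruskal-Wallis H matches the hand computation without ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-9)
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("small-sample p agrees with brute-force permutation enumeration", {
  set.seed(31)
  for (sizes in list(c(3, 3, 2), c(4, 4), c(2, 3, 2))) {
    x <- sample(100, sum(sizes))          # no ties
    groups <- split(x, rep(seq_along(sizes), sizes))
    kw <- kruskal_wallis(groups)          # auto -> exact for n <= 8
    expect_equal(kw$method, "exact")
    # oracle: definition-formula H over every labeled partition, counted
    # via combinations of positions (independent of the package internals)
    H_obs <- kw_h_definition(groups)
    pos <- seq_len(sum(sizes))
    tally <- c(ge = 0, tot = 0)
    pick <- function(rem, gi, acc) {
      if (gi == length(sizes)) {
        gs <- lapply(c(acc, list(rem)), function(i) x[i])
        tally["tot"] <<- tally["tot"] + 1
        if (kw_h_definition(gs) >= H_obs - 1e-9) tally["ge"] <<- tally["ge"] + 1
        return(invisible())
      }
      for (sel in utils::combn(rem, sizes[gi], simplify = FALSE))
        pick(setdiff(rem, sel), gi + 1, c(acc, list(sel)))
    }
    pick(pos, 1, list())
    expect_equal(kw$p.value, unname(tally["ge"] / tally["tot"]),
                 tolerance = 1e-9)
  }
})

test_that("Dunn post hoc is symmetric, gated, and Holm-dominated", {
  identical_groups <- list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5))
  d0 <- dunn_posthoc(identical_groups, gate = FALSE)
  expect_true(all(d0$p_unadjusted[upper.tri(d0$p_unadjusted)] == 1))
  set.seed(7)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
  d <- dunn_posthoc(g)
  expect_true(d$run)
  expect_equal(d$p_unadjusted, t(d$p_unadjusted))
  expect_equal(d$z, -t(d$z))
  up <- upper.tri(d$p_unadjusted)
  expect_true(all(d$p_unadjusted[up] <= d$p_holm[up] + 1e-12))
  # the shifted group separates from both others more than they separate
  # from each other
  expect_lt(d$p_unadjusted["a", "c"], d$p_unadjusted["a", "b"])
  expect_lt(d$p_unadjusted["b", "c"], d$p_unadjusted["a", "b"])
  # gating: null groups with high omnibus p do not run
  gn <- list(a = c(1, 3, 2, 5), b = c(2, 4, 1, 3), c = c(3, 1, 4, 2))
  dn <- dunn_posthoc(gn)
  if (!dn$run) expect_true(all(is.na(dn$p_unadjusted)))
  expect_error(dunn_posthoc(list(a = numeric(), b = 1:3)), "non-empty")
})

test_that("trend test: exact fit, direction, and level drop", {
  # perfectly decreasing toward shorter CL, no within-level spread
  v <- rep(c(80, 75, 70, 65), each = 4)
  cl <- rep(c(400, 300, 250, 200), each = 4)
  tr <- trend_test(v, cl)
  expect_lt(tr$p, 1e-10)
  expect_lt(tr$slope, 0)
  expect_error(trend_test(c(1, 2, 3, 4), c(400, 400, 300, 300)), ">= 3")
})

test_that("Teichholz ejection fraction matches the closed form", {
  # V(D) = 7/(2.4 + D) D^3: V(1.5) = 6.05769 mL, V(1.0) = 2.05882 mL
  v <- function(D) 7 / (2.4 + D) * D^3
  expect_equal(teichholz_ef(1.5, 1.0), 100 * (v(1.5) - v(1)) / v(1.5))
  expect_equal(teichholz_ef(1.5, 1.0), 66.01, tolerance = 1e-2)
  expect_equal(teichholz_ef(1.2, 1.2), 0)
  expect_gt(teichholz_ef(1.5, 1e-6), 99.99)
  expect_equal(teichholz_ef(15, 10, units = "mm"), teichholz_ef(1.5, 1.0))
  expect_error(teichholz_ef(1.0, 1.5), "exceed")
  # strictly decreasing in end-systolic diameter
  efs <- teichholz_ef(rep(1.6, 20), seq(0.4, 1.5, length.out = 20))
  expect_true(all(diff(efs) < 0))
})

test_that("group summaries report n-1 SDs and correct group sizes", {
  d <- expand.grid(subject_id = sprintf("s%02d", 1:18), cl_ms = c(400, 300, 250))
  d$group <- rep(rep(c("sham", "rdn", "hf", "rdn_hf"), c(5, 5, 4, 4)), 3)
  set.seed(2)
  d$apd80_ms <- 70 + (d$group == "hf") * 25 + rnorm(nrow(d), 0, 3)
  gt <- summarize_groups(d, "apd80_ms")
  s <- gt$summary
  expect_equal(s$sham_n, rep(5L, 3))
  expect_equal(s$hf_n, rep(4L, 3))
  expect_equal(s$rdn_hf_n, rep(4L, 3))
  one <- d[d$cl_ms == 400 & d$group == "sham", "apd80_ms"]
  expect_equal(s$sham_mean[1], mean(one))
  expect_equal(s$sham_sd[1], sd(one))     # n-1 denominator
  expect_true(all(s$p_value < 0.05))      # hf clearly separated
  # single-subject group: SD missing, mean equals the raw value
  d2 <- data.frame(subject_id = c("a", "b"), group = c("g1", "g2"),
                   cl_ms = 400, apd80_ms = c(70, 90))
  gt2 <- summarize_groups(d2, "apd80_ms")
  expect_true(is.na(gt2$summary$g1_sd))
  expect_equal(gt2$summary$g1_mean, 70)
})
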