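# Sweep pipelines: sampling, trends, logic gates, cascade comparison.

test_that("evaluate_dora returns the per-set result row", {
  ma <- model_spec("mass_action", "none")
  r <- evaluate_dora(kinetic_parameters(), ma, params_id = "base")
  expect_named(r, c("params_id", "metric_mG", "metric_tG", "mG_activation"))
  expect_identical(r$params_id, "base")
  expect_gt(r$metric_mG, 0)
  expect_gte(r$metric_tG, r$metric_mG)  # mass-action cascade ordering
  expect_equal(r$mG_activation, 0.5, tolerance = 1e-10)
})

test_that("parameter-space sampling is seeded and leaves no RNG trace", {
  ma <- model_spec("mass_action", "none")
  expect_identical(sample_parameter_space(0, ma), list())
  a <- sample_parameter_space(5, ma, seed = 10)
  b <- sample_parameter_space(5, ma, seed = 10)
  expect_equal(a, b)
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(sample_parameter_space(5, ma, seed = 10))
  expect_identical(stats::runif(1), x1)
  # Hill spaces include the receptor rate by default
  hset <- sample_parameter_space(3, model_spec("hill"), seed = 1)
  expect_false(all(vapply(hset, function(p) p$k_on_R == 1, logical(1))))
})

test_that("sampled activation levels cover the unit interval non-degenerately", {
  ma <- model_spec("mass_action", "none")
  sets <- sample_parameter_space(100, ma, seed = 5)
  acts <- vapply(sets, function(p) activation_levels(p, ma)[["mG_max"]],
                 numeric(1))
  expect_true(all(acts > 0 & acts < 1))
  expect_lt(min(acts), 0.3)
  expect_gt(max(acts), 0.8)
})

test_that("raising mGAP production enhances alignment monotonically", {
  ma <- model_spec("mass_action", "none")
  tab <- sweep_single_parameter("k_on_mGAP", 10^seq(-2, 0, length.out = 9),
                                kinetic_parameters(), ma)
  expect_true(all(is.na(tab$error)))
  expect_true(all(diff(tab$mG_activation) < 0))
  expect_true(all(diff(tab$metric_mG) < 0))
  expect_true(all(diff(tab$metric_tG) < 0))
  expect_identical(classify_trend(tab$metric_mG)$label, "decreasing")
})

test_that("single-point sweeps classify as flat and bad names error", {
  ma <- model_spec("mass_action", "none")
  tab <- sweep_single_parameter("k_on_mGAP", 0.5, kinetic_parameters(), ma)
  expect_identical(nrow(tab), 1L)
  expect_identical(classify_trend(tab$metric_mG)$label, "flat")
  expect_error(sweep_single_parameter("k_zap", 1:2, kinetic_parameters(), ma),
               "unknown kinetic parameter")
})

test_that("per-point solver failures are recorded, not fatal", {
  ma <- model_spec("mass_action", "none")
  # k_off_mGAP = 0 violates the parameter invariants at that point only
  tab <- sweep_single_parameter("k_off_mGAP", c(1, 0, 2),
                                kinetic_parameters(), ma)
  expect_true(is.na(tab$error[1]) && is.na(tab$error[3]))
  expect_false(is.na(tab$error[2]))
  expect_true(is.na(tab$metric_mG[2]))
})

test_that("Hill mGAP sweeps reproduce the three activation regimes", {
  hs <- model_spec("hill", "none")
  kg <- 10^seq(log10(0.01), log10(1), length.out = 9)
  run <- function(regime, seed) {
    p <- preset_for_regime(regime, hs, seed = seed,
                           base = kinetic_parameters(k_on_mGAP = 0.01),
                           sample_names = c("k_on_R", "k_on_mG", "k_on_tG"))
    classify_trend(sweep_single_parameter("k_on_mGAP", kg, p, hs)$metric_mG)
  }
  expect_identical(run("high_activation", 1)$label, "decreasing")
  expect_identical(run("intermediate_activation", 4)$label, "dec_then_inc")
  expect_identical(run("low_activation", 3)$label, "increasing")
})

test_that("trend classification follows the sign pattern with tolerance", {
  expect_identical(classify_trend(c(3, 2, 1))$label, "decreasing")
  expect_identical(classify_trend(c(1, 2, 3))$label, "increasing")
  expect_identical(classify_trend(c(1, 0.5, 0.8))$label, "dec_then_inc")
  expect_identical(classify_trend(c(0.5, 1, 0.2))$label, "inc_then_dec")
  # sub-tolerance wiggles count as flat
  eps <- 1e-4
  expect_identical(classify_trend(c(1, 1 + eps, 1 - eps))$label, "flat")
  # classification is invariant to appending sub-tolerance values
  expect_identical(classify_trend(c(3, 2, 1, 1 + 1e-5))$label, "decreasing")
  # two or more sign changes: ambiguous, label NA
  amb <- classify_trend(c(1, 2, 1, 2))
  expect_true(amb$ambiguous)
  expect_true(is.na(amb$label))
  expect_false(classify_trend(c(3, 2, 1))$ambiguous)
  expect_error(classify_trend(numeric(0)), "at least 2")
})

test_that("binned means degenerate correctly and track the one-to-one map", {
  same <- data.frame(mG_activation = c(0.41, 0.42, 0.43),
                     metric_mG = rep(0.2, 3))
  b <- binned_mean_metric(same, n_bins = 1)
  expect_equal(b$mean, 0.2)
  expect_equal(b$sd, 0)
  expect_identical(b$n, 3L)
  # a gap in activation leaves interior bins empty and flagged
  gap <- data.frame(mG_activation = c(0.1, 0.11, 0.9, 0.91),
                    metric_mG = c(0.1, 0.1, 0.4, 0.4))
  bg <- binned_mean_metric(gap, n_bins = 8)
  expect_true(length(attr(bg, "empty_bins")) > 0)
  # mass-action no-feedback space: binned means increase with activation
  ma <- model_spec("mass_action", "none")
  sets <- sample_parameter_space(80, ma, seed = 5)
  res <- do.call(rbind, lapply(sets, evaluate_dora, spec = ma))
  bb <- binned_mean_metric(res)
  expect_true(all(diff(bb$mean) > 0))
})

test_that("feedback worsens the mean metric at matched activation bins", {
  ma_none <- model_spec("mass_action", "none")
  ma_and <- model_spec("mass_action", "and")
  sn <- c("k_on_mG", "k_on_tG", "k_on_mGAP")
  rng <- utils::modifyList(default_ranges(),
                           list(k_feedback = c(1e-1, 10^2.6)))
  ev <- function(sets, sp) do.call(rbind, lapply(sets, evaluate_dora,
                                                 spec = sp))
  r0 <- ev(sample_parameter_space(200, ma_none, sample_names = sn,
                                  seed = 21), ma_none)
  r1 <- ev(sample_parameter_space(200, ma_and,
                                  sample_names = c(sn, "k_feedback"),
                                  seed = 21, ranges = rng), ma_and)
  breaks <- seq(0, 1, by = 0.1)
  i0 <- cut(r0$mG_activation, breaks, labels = FALSE)
  i1 <- cut(r1$mG_activation, breaks, labels = FALSE)
  for (b in 1:10) {
    if (sum(i0 == b, na.rm = TRUE) >= 5 && sum(i1 == b, na.rm = TRUE) >= 5) {
      expect_gte(mean(r1$metric_mG[i1 == b], na.rm = TRUE),
                 mean(r0$metric_mG[i0 == b], na.rm = TRUE))
    }
  }
})

test_that("matched OR strength reproduces the AND activation level", {
  for (kin in c("mass_action", "hill")) {
    sp <- model_spec(kin, "and")
    for (seed in c(1, 6)) {
      p <- sample_parameter_space(1, sp, seed = seed,
                                  base = kinetic_parameters(k_on_mGAP = 0.01))[[1]]
      for (k_and in c(0.5, 20)) {
        k_or <- match_or_feedback_strength(p, sp, k_and)
        k_cf <- match_or_feedback_strength(p, sp, k_and,
                                           method = "closed_form")
        # the root polish is limited by the activation solver's noise
        # floor when the activation barely depends on k_or (Hill, tiny
        # matched strengths); mass action stays at the closed form
        tol_k <- if (kin == "mass_action") 1e-8 else 1e-4
        expect_equal(k_or, k_cf, tolerance = tol_k)
        p_and <- p; p_and$k_feedback <- k_and
        p_or <- p; p_or$k_feedback <- k_or
        act_and <- activation_levels(p_and, model_spec(kin, "and"))[["mG_max"]]
        act_or <- activation_levels(p_or, model_spec(kin, "or"))[["mG_max"]]
        expect_lt(abs(act_and - act_or), 1e-8)
      }
    }
  }
  expect_identical(match_or_feedback_strength(kinetic_parameters(),
                                              model_spec("mass_action"), 0), 0)
})

test_that("logic-gate comparison: OR never worse than AND under mass action", {
  sp <- model_spec("mass_action", "and")
  sets <- sample_parameter_space(20, sp, seed = 31,
                                 base = kinetic_parameters(k_on_mGAP = 0.01),
                                 sample_names = c("k_on_mG", "k_on_tG"))
  set.seed(32)
  k_and <- 10^stats::runif(20, -2, 2.6)
  cmp <- compare_logic_gates(sets, k_and, sp)
  expect_true(all(is.na(cmp$pairs$error)))
  expect_true(all(cmp$pairs$metric_or <= cmp$pairs$metric_and + 1e-10))
  expect_gt(cmp$mean_metric_and, 0)
  # zero feedback strengths land exactly on the diagonal
  cmp0 <- compare_logic_gates(sets[1:3], 0, sp)
  expect_equal(cmp0$pairs$metric_or, cmp0$pairs$metric_and, tolerance = 1e-12)
  expect_lt(cmp0$mean_diagonal_distance, 1e-12)
})

test_that("the matched-gate inequality holds pointwise along the curve", {
  # (k_OR / k_AND) (1/h1(y) + 1/h2(y)) >= 1 for y = mG*_ss(S) <= mG*_ss,max
  sp <- model_spec("mass_action", "and")
  for (seed in c(2, 8)) {
    p <- sample_parameter_space(1, sp, seed = seed,
                                base = kinetic_parameters(k_on_mGAP = 0.01))[[1]]
    k_and <- 5
    k_or <- match_or_feedback_strength(p, sp, k_and)
    p_and <- p; p_and$k_feedback <- k_and
    drc <- dose_response(p_and, sp)
    y <- drc$curve$mG_star
    y <- y[y > 1e-12]
    b_M <- derived_constants(p, sp)$b_M
    h1 <- (p$k_on_tGEF / p$k_off_tGEF) * y
    h2 <- y / (y + b_M)
    expect_true(all((k_or / k_and) * (1 / h1 + 1 / h2) >= 1 - 1e-9))
  }
})

test_that("cascade comparison: tGTPase never better under mass action", {
  for (logic in c("none", "and")) {
    sp <- model_spec("mass_action", logic)
    sets <- sample_parameter_space(40, sp, seed = 13)
    if (logic == "and") {
      sets <- lapply(sets, function(p) {
        p$k_feedback <- 2
        p
      })
    }
    res <- do.call(rbind, lapply(sets, evaluate_dora, spec = sp))
    cc <- compare_cascade(res)
    expect_identical(cc$n_below, 0L)
    expect_gt(cc$n_above, 0L)
  }
})

test_that("Hill cascades can favor the tGTPase at low activation", {
  hs <- model_spec("hill", "none")
  sets <- sample_parameter_space(150, hs, seed = 17)
  res <- evaluate_space(sets, hs)
  cc <- compare_cascade(res)
  expect_gt(cc$n_below, 0L)
  # below-diagonal cases concentrate at low activation
  expect_lt(mean(cc$below_diagonal$mG_activation),
            stats::median(res$mG_activation, na.rm = TRUE))
  # a steeper Hill coefficient lifts the attainable alignment floor
  hs3 <- model_spec("hill", "none", hill_spec(K = 0.5, n = 3))
  sets3 <- sample_parameter_space(150, hs3, seed = 17)
  res3 <- evaluate_space(sets3, hs3)
  expect_gt(compare_cascade(res3)$min_metric_mG, cc$min_metric_mG)
})

test_that("feedback grid starts at zero and spans the study range", {
  g <- feedback_grid()
  expect_identical(g[1], 0)
  expect_equal(max(g), 10^2.6)
  expect_true(all(diff(g) > 0))
  expect_length(g, 9)
})
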