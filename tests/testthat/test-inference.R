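test_that("Type II Wald chi-squares match the brute-force GLS oracle on the 12-row fixture", {
  d <- wald_fixture()
  fit <- lme4::lmer(y ~ phase * location + (1 | seizure), data = d, REML = TRUE)
  a <- car::Anova(fit, type = "II", test.statistic = "Chisq")
  oracle <- oracle_type2_wald(fit, d)
  expect_lt(max(abs(a$Chisq - oracle[rownames(a)])), 1e-8)
})

test_that("Wald statistics are invariant to location label permutation", {
  tab <- make_table(n_seizures = 6, effect = 0.8, seed = 2)
  w1 <- type2_wald(fit_lmm(tab, transform = "identity"))
  tab2 <- tab
  relab <- c(Fp1 = "Z1", Fp2 = "Z2", C3 = "Z3", C4 = "Z4",
             T3 = "Z5", T4 = "Z6", O1 = "Z7", O2 = "Z8")
  el <- tab2$level == "electrode"
  tab2$location[el] <- unname(relab[tab2$location[el]])
  w2 <- type2_wald(fit_lmm(tab2, transform = "identity"))
  expect_equal(w1$chisq, w2$chisq, tolerance = 1e-8)
  expect_equal(w1$df, w2$df)
})

test_that("model fitting validates its inputs and degenerate responses", {
  tab <- make_table(n_seizures = 4, seed = 3)
  expect_error(fit_lmm(tab[tab$phase != "onset", ]), "four ictal phase")
  one <- tab[tab$seizure_index == 1, ]
  expect_error(fit_lmm(one), "at least 2 seizures")
  const <- tab
  const$value <- 0.5
  expect_error(fit_lmm(const), "degenerate response")
  low <- tab
  low$value[1] <- -7.5
  expect_error(fit_lmm(low), "below -7")
  lowr <- tab
  lowr$value[lowr$level == "region"][1] <- -1.5
  expect_error(fit_lmm(lowr, level = "region"), "below -1")
})

test_that("the auto transform reacts to residual skewness and respects bounds", {
  tab <- make_table(n_seizures = 8, seed = 4)
  f0 <- fit_lmm(tab)
  expect_identical(f0$transform, "identity")   # symmetric noise
  skewed <- tab
  skewed$value <- exp(4 * skewed$value) - 1    # heavy right tail, > -1 > -7
  f1 <- fit_lmm(skewed)
  expect_identical(f1$transform, "log")
  at_bound <- skewed
  at_bound$value[at_bound$level == "electrode"][1] <- -7
  f2 <- fit_lmm(at_bound)
  expect_identical(f2$transform, "sqrt")
  expect_error(fit_lmm(at_bound, transform = "log"), "undefined")
})

test_that("Dunnett contrasts: 3 per location, monotone adjustment, below Bonferroni", {
  tab <- make_table(n_seizures = 8, effect = 1.0, effect_location = "C3", seed = 5)
  fit <- fit_lmm(tab, transform = "identity")
  dun <- dunnett_vs_termination(fit)
  expect_equal(nrow(dun), 3 * 8)
  expect_setequal(unique(dun$phase), c("pre_ictal", "onset", "post_ictal"))
  expect_true(all(table(dun$location) == 3))
  expect_true(all(dun$p_adj >= dun$p_raw - 1e-12))
  expect_true(all(dun$p_adj <= pmin(1, 3 * dun$p_raw) + 1e-6))
  # determinism of the multivariate-t quadrature under the internal seed
  dun2 <- dunnett_vs_termination(fit)
  expect_equal(dun$p_adj, dun2$p_adj, tolerance = 1e-12)
  # the planted C3 elevation is found with positive sign
  c3 <- dun[dun$location == "C3", ]
  expect_true(all(c3$estimate > 0))
  expect_true(all(c3$p_adj < 0.05))
})

test_that("call rules: all-three vs any-one, sign gating, trivial cases", {
  mk_dun <- function(est, p) {
    structure(data.frame(location = rep("C3", 3),
                         phase = c("pre_ictal", "onset", "post_ictal"),
                         estimate = est, se = 0.1, p_raw = p, p_adj = p),
              class = c("dunnett_result", "data.frame"))
  }
  expect_false(call_terminal_hypersync(mk_dun(c(1, 1, 1), rep(1, 3)))[["C3"]])
  expect_true(call_terminal_hypersync(mk_dun(c(1, 1, 1), c(0.01, 0.02, 0.001)))[["C3"]])
  # significant but termination LOWER -> negative call
  expect_false(call_terminal_hypersync(mk_dun(c(-1, -1, -1), rep(0.001, 3)))[["C3"]])
  mixed <- mk_dun(c(1, 1, 1), c(0.01, 0.5, 0.01))
  expect_false(call_terminal_hypersync(mixed, rule = "all")[["C3"]])
  expect_true(call_terminal_hypersync(mixed, rule = "any")[["C3"]])
})

test_that("calls are identical under identity and log transforms for small values", {
  tab <- make_table(n_seizures = 8, effect = 0.06, sd = 0.02, seed = 6)
  tab$value <- pmax(pmin(tab$value, 0.095), -0.095)  # |v| < 0.1
  fi <- fit_lmm(tab, transform = "identity")
  fl <- fit_lmm(tab, transform = "log")
  ci <- call_terminal_hypersync(dunnett_vs_termination(fi))
  cl <- call_terminal_hypersync(dunnett_vs_termination(fl))
  expect_identical(ci, cl)
})

test_that("a pooled multi-patient table uses crossed random intercepts", {
  tab <- rbind(make_table(n_seizures = 4, seed = 7, patient_id = "p01"),
               make_table(n_seizures = 4, seed = 8, patient_id = "p02"))
  fit <- fit_lmm(tab, transform = "identity")
  expect_true(fit$pooled)
  expect_setequal(names(lme4::ranef(fit$fit)), c("patient_id", "seizure"))
  w <- type2_wald(fit)
  expect_setequal(w$term, c("phase", "location", "phase:location"))
  expect_true(all(w$chisq >= 0))
  expect_true(all(w$p > 0 & w$p <= 1))
})
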