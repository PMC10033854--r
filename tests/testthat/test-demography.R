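test_that("survival components follow the resilience power laws", {
  sc <- survival_components(S = 0, D = 0, r_cancer_to_dc = 2,
                            r_senesc_to_cs = 3, ext_m = 0.05)
  expect_equal(unlist(sc), c(p_cancer = 1, p_ageing = 1, p_ext = 0.95))
  expect_equal(survival_components(0, 0.3, 2, 1)$p_cancer, 0.91)
  expect_equal(survival_components(0.5, 0, 1, 3)$p_ageing, 0.875)
  # 0^0 convention: an undamaged organism survives even at exponent 0
  sc0 <- survival_components(S = 0, D = 0, r_cancer_to_dc = 1,
                             r_senesc_to_cs = 0)
  expect_equal(sc0$p_ageing, 1)
  expect_equal(survival_components(0.2, 0, 1, 0)$p_ageing, 0)
})

test_that("fertility declines linearly and clamps at zero", {
  expect_equal(fertility(123, 0), 1)
  expect_equal(fertility(10, 0.02), 0.8)
  expect_equal(fertility(100, 0.02), 0)  # raw -1
})

test_that("LRS reduces to a geometric life expectancy without damage", {
  p <- param_set(alpha = 0, gamma = 0.5, r_cancer_to_dc = 1,
                 r_senesc_to_cs = 1, r_damage_to_cs = 1, ext_m = 0.1)
  sched <- demographic_schedule(p, sigma = 0)
  expect_equal(lrs(sched), 10, tolerance = 1e-6)  # sum 0.9^x = 1/extM
  # without reproductive senescence LRS is exactly life expectancy
  expect_identical(lrs(sched), sum(sched$lx))
})

test_that("demographic sums match the spreadsheet oracle", {
  pars <- random_params(25, seed = 55)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    ps <- param_set(alpha = p$alpha, gamma = p$gamma,
                    r_cancer_to_dc = p$r_cancer, r_senesc_to_cs = p$r_senesc,
                    r_damage_to_cs = p$r_damage, ext_m = p$ext_m,
                    senesc_repro = p$senesc_repro)
    sched <- demographic_schedule(ps, sigma = p$sigma, horizon = 400)
    ref_path <- oracle_path(p$alpha, p$gamma, p$sigma, p$r_damage,
                            n_steps = nrow(sched) - 1)
    ref <- oracle_demography(ref_path, p$r_cancer, p$r_senesc, p$ext_m,
                             p$senesc_repro)
    expect_equal(sched$lx, ref$lx, tolerance = 1e-12)
    expect_equal(suppressWarnings(lrs(sched)), ref$lrs, tolerance = 1e-12)
    expect_equal(suppressWarnings(cancer_prevalence(sched)), ref$prev,
                 tolerance = 1e-12)
  }
})

test_that("total mortality mass is conserved", {
  pars <- random_params(25, seed = 19)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    ps <- param_set(alpha = max(p$alpha, 1e-3), gamma = min(p$gamma, 0.99),
                    r_cancer_to_dc = p$r_cancer, r_senesc_to_cs = p$r_senesc,
                    r_damage_to_cs = p$r_damage, ext_m = p$ext_m)
    sched <- demographic_schedule(ps, sigma = p$sigma)
    died <- sum(sched$lx * (1 - sched$p_cancer * sched$p_ageing * sched$p_ext))
    n <- nrow(sched)
    l_end <- sched$lx[n] * sched$p_cancer[n] * sched$p_ageing[n] * sched$p_ext[n]
    expect_equal(died, 1 - l_end, tolerance = 1e-9)
    expect_lt(l_end, 1e-6)
    expect_true(all(diff(sched$lx) <= 1e-15))
  }
})

test_that("LRS decreases termwise in extrinsic mortality and reproductive senescence", {
  pars <- random_params(10, seed = 77)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    base <- param_set(alpha = max(p$alpha, 1e-3), gamma = min(p$gamma, 0.99),
                      r_cancer_to_dc = p$r_cancer, r_senesc_to_cs = p$r_senesc,
                      r_damage_to_cs = p$r_damage, ext_m = 0.01,
                      senesc_repro = 0.001)
    v0 <- lrs(demographic_schedule(base, sigma = p$sigma))
    up_ext <- base; up_ext$ext_m <- 0.05
    up_sr <- base; up_sr$senesc_repro <- 0.01
    expect_lte(lrs(demographic_schedule(up_ext, sigma = p$sigma)), v0)
    expect_lte(lrs(demographic_schedule(up_sr, sigma = p$sigma)), v0)
  }
})

test_that("cause-specific cumulative incidence accumulates complements", {
  # no damage ever: cancer cumulative incidence identically zero
  p <- param_set(alpha = 0, gamma = 0.5, r_cancer_to_dc = 1,
                 r_senesc_to_cs = 1, r_damage_to_cs = 1, ext_m = 0.1)
  ci <- cumulative_cause_incidence(demographic_schedule(p, sigma = 0.2),
                                   "cancer")
  expect_true(all(ci$cum_incidence == 0))
  # two-age complement by hand
  sched <- data.frame(x = 0:1, p_cancer = c(0.9, 0.8), p_ageing = c(1, 1))
  ci <- cumulative_cause_incidence(sched, "cancer")
  expect_equal(ci$cum_incidence, c(0, 0.1))
  # general non-decreasing property
  ps <- param_set(alpha = 0.005, gamma = 0.8, r_cancer_to_dc = 2,
                  r_senesc_to_cs = 2, r_damage_to_cs = 3)
  s2 <- demographic_schedule(ps, sigma = 0.05, include_ext_m = FALSE)
  for (cause in c("cancer", "ageing")) {
    ci <- cumulative_cause_incidence(s2, cause)
    expect_true(all(diff(ci$cum_incidence) >= -1e-15))
  }
})

test_that("derived life expectancies expose closed forms and cap flags", {
  p <- param_set(alpha = 0.006, gamma = 0.765, r_cancer_to_dc = 1,
                 r_senesc_to_cs = 1, r_damage_to_cs = 1, ext_m = 0.000286)
  m <- life_expectancies(p, sigma = 0.01)
  expect_equal(m$e0_ext, 1 / 0.000286, tolerance = 1e-12)
  expect_equal(m$delta_r, 0)
  expect_false(m$capped)
  expect_true(is.finite(m$e0_captive) && m$e0_captive > 0)
  # alpha = 0: the cancer-only sum never converges and must be flagged
  p0 <- param_set(alpha = 0, gamma = 0.5, r_cancer_to_dc = 1,
                  r_senesc_to_cs = 1, r_damage_to_cs = 1)
  m0 <- life_expectancies(p0, horizon = 2000)
  expect_true(m0$capped)
})
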