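# Robust-design misidentification likelihood, fitting, ranking, averaging

test_that("model structures validate and count parameters correctly", {
  m <- rd_model(phi = "sex", p = "sex_season", c = "sex_season",
                alpha = "sex_season", f0 = "sex")
  expect_s3_class(m, "rd_model")
  expect_error(rd_model(phi = "season"), "invalid structure")
  expect_error(rd_model(alpha = rd_fixed(1.4)), "probability")
  det <- array(0L, c(4, 2, 3)); det[, 1, 1] <- 1L; det[1:2, 2, 2] <- 1L
  h <- manual_histories(det, c("F", "F", "M", "M"))
  # sex_season p/c/alpha: 4 each; f0 sex: 2; phi sex: 2; gammas: 1+1
  expect_length(rd_par_names(h, m), 4 * 3 + 2 + 2 + 2)
  # no-movement constraint reduces K by 2
  m3 <- rd_model(phi = "sex", gamma_prime = rd_fixed(1),
                 gamma_dprime = rd_fixed(0), p = "sex_season",
                 c = "sex_season", alpha = "sex_season", f0 = "sex")
  expect_length(rd_par_names(h, m3), length(rd_par_names(h, m)) - 2)
})

test_that("emission recursion matches a Monte-Carlo capture-process oracle", {
  set.seed(14)
  K <- 3; p <- 0.4; c_ <- 0.6; alpha <- 0.8
  n_mc <- 40000
  pats <- matrix(0L, n_mc, K)
  for (i in seq_len(n_mc)) {
    caught <- FALSE
    for (j in 1:K) {
      pr <- if (caught) c_ else p
      if (runif(1) < pr) {
        caught <- TRUE
        if (runif(1) < alpha) pats[i, j] <- 1L  # recorded; else ghost spawn
      }
    }
  }
  allpat <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  em <- haremark:::.rd_emission(allpat, rep(p, K), rep(c_, K), alpha)
  keys <- apply(allpat, 1, paste, collapse = "")
  obs <- table(factor(apply(pats, 1, paste, collapse = ""), levels = keys))
  for (r in seq_along(keys)) {
    pr <- em$q[r]
    expect_lt(abs(obs[r] / n_mc - pr), 3 * sqrt(pr * (1 - pr) / n_mc) + 1e-3)
  }
  expect_equal(sum(em$q), 1, tolerance = 1e-12)
  # expected ghost spawns per occasion, same oracle
  expect_equal(em$q0, unname(em$q[keys == "000"]))
})

test_that("alpha = 1 reduces each closed component to the standard closed likelihood", {
  # 5-individual single-session instance, enumeration-based oracle
  det <- array(0L, c(5, 1, 3))
  det[1, 1, ] <- c(1, 1, 0); det[2, 1, ] <- c(0, 1, 1)
  det[3, 1, ] <- c(1, 0, 1); det[4, 1, ] <- c(0, 0, 1)
  det[5, 1, ] <- c(1, 1, 1)
  h <- manual_histories(det, rep("F", 5))
  m <- rd_model(phi = rd_fixed(1), gamma_prime = rd_fixed(1),
                gamma_dprime = rd_fixed(0), p = "constant", c = "constant",
                alpha = rd_fixed(1), f0 = "constant")
  p <- 0.35; c_ <- 0.55; f0 <- 2.3
  par <- c(qlogis(p), qlogis(c_), log(f0))
  names(par) <- rd_par_names(h, m)
  got <- -rd_negloglik(par, h, m)
  # independent closed-model likelihood: sequential capture probabilities
  closed_pattern <- function(w, p, c_) {
    caught <- FALSE; pr <- 1
    for (j in seq_along(w)) {
      cap <- if (caught) c_ else p
      pr <- pr * if (w[j] == 1) cap else (1 - cap)
      if (w[j] == 1) caught <- TRUE
    }
    pr
  }
  q0 <- closed_pattern(c(0, 0, 0), p, c_)
  pats <- lapply(1:5, function(i) det[i, 1, ])
  ll_pat <- sum(log(vapply(pats, closed_pattern, numeric(1), p = p, c_ = c_)))
  xlx <- function(z) if (z > 0) z * log(z) else 0
  D <- 5
  ll_count <- xlx(D + f0) - xlx(f0) - xlx(D) + f0 * log(q0) +
    D * log1p(-q0)
  # single session: every history starts here, so patterns enter
  # conditionally on detection and the count term restores the Bernoullis
  want <- ll_pat - D * log1p(-q0) + ll_count
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("no-movement, certain-survival likelihood separates across sessions", {
  # all individuals detected in every session: open component is inert
  det <- array(0L, c(4, 2, 2))
  det[, 1, 1] <- 1L; det[, 2, 2] <- 1L
  det[1:2, 1, 2] <- 1L; det[3, 2, 1] <- 1L
  h <- manual_histories(det, rep("F", 4), seasons = c("spring", "spring"))
  m <- rd_model(phi = rd_fixed(1), gamma_prime = rd_fixed(1),
                gamma_dprime = rd_fixed(0), p = "constant", c = "constant",
                alpha = rd_fixed(1), f0 = "constant")
  par <- c(qlogis(0.3), qlogis(0.5), log(1.7))
  got <- -rd_negloglik(par, h, m)
  # per-session components computed independently on single-session data
  part <- vapply(1:2, function(t) {
    d1 <- det[, t, , drop = FALSE]
    dim(d1) <- c(4, 1, 2)
    h1 <- manual_histories(d1, rep("F", 4), seasons = "spring")
    -rd_negloglik(par, h1, m)
  }, numeric(1))
  # first-session conditioning differs between the joint fit (conditioning
  # at each animal's first detection only) and the separate fits; account
  # for the session-2 conditioning factor explicitly
  em <- haremark:::.rd_emission(matrix(0L, 1, 2), rep(0.3, 2), rep(0.5, 2), 1)
  expect_equal(got, sum(part) + 4 * log(1 - em$q0), tolerance = 1e-10)
})

test_that("Lincoln-Petersen instance: MLE abundance is n1*n2/m2 = 100", {
  det <- array(0L, c(70, 1, 2))
  det[1:30, 1, 1] <- 1L
  det[31:50, 1, 2] <- 1L
  det[51:70, 1, 1:2] <- 1L
  h <- manual_histories(det, rep("F", 70), seasons = "spring")
  m <- rd_model(phi = rd_fixed(1), gamma_prime = rd_fixed(1),
                gamma_dprime = rd_fixed(0), p = "occasion", c = "equal_p",
                alpha = rd_fixed(1), f0 = "constant")
  fit <- rd_fit(h, m)
  expect_true(fit$convergence)
  ab <- derived_abundance(fit, area_km2 = 3.5)
  expect_equal(ab$N_F, 100, tolerance = 0.001)
  expect_equal(ab$density, 100 / 3.5, tolerance = 0.001)
  # p per occasion recovers n_j / N
  p_est <- fit$real$estimate[fit$real$parameter == "p"]
  expect_equal(p_est, c(0.5, 0.4), tolerance = 0.001)
  # refitting from the returned MLE is a fixed point
  nll1 <- rd_negloglik(coef(fit), h, m)
  expect_equal(-nll1, fit$logLik, tolerance = 1e-6)
})

test_that("error-free closed simulation drives free alpha to the boundary", {
  cfg <- errorfree_config(63, n_females = 30, n_males = 30, n_pso = 2,
                          p = 0.4)
  truth <- simulate_population(cfg)
  h <- simulated_histories(truth)
  m <- rd_model(phi = rd_fixed(1), gamma_prime = rd_fixed(1),
                gamma_dprime = rd_fixed(0), p = "constant", c = "constant",
                alpha = "constant", f0 = "constant")
  fit <- suppressWarnings(rd_fit(h, m, n_starts = 1, hessian = FALSE))
  a <- fit$real$estimate[fit$real$parameter == "alpha"]
  expect_gt(a, 0.98)
})

test_that("forward-recursion state distributions stay normalized", {
  # transition matrix rows sum to 1 for interior parameter values
  for (phi in c(0.3, 0.8, 1)) {
    for (gdp in c(0, 0.2)) {
      for (gp in c(0.5, 1)) {
        M <- haremark:::.rd_transition(phi, gdp, gp)
        expect_equal(rowSums(M), c(1, 1, 1))
      }
    }
  }
  # emission q over all patterns sums to 1 even with misidentification
  for (alpha in c(0.6, 0.9)) {
    allpat <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
    em <- haremark:::.rd_emission(allpat, rep(0.3, 4), rep(0.45, 4), alpha)
    expect_equal(sum(em$q), 1, tolerance = 1e-12)
  }
})

test_that("AICc ranking reproduces the published arithmetic", {
  rk <- rd_rank(c(1779.2, 1780.8, 1782.1), K = c(12, 16, 20))
  expect_equal(rk$dAICc, c(0, 1.6, 2.9), tolerance = 1e-9)
  expect_equal(rk$model_lik[1], 1)
  expect_equal(round(rk$model_lik[2], 2), 0.45)
  expect_equal(sum(rk$weight), 1)
  # ranking is invariant to input order
  rk2 <- rd_rank(c(1782.1, 1779.2, 1780.8), K = c(20, 12, 16))
  expect_equal(rk2$AICc, rk$AICc)
  # AICc formula: -2 logLik + 2K + small-sample correction
  det <- array(0L, c(6, 1, 3)); det[, 1, 1] <- 1L; det[1:3, 1, 2] <- 1L
  h <- manual_histories(det, rep("F", 6))
  m <- rd_model(phi = rd_fixed(1), gamma_prime = rd_fixed(1),
                gamma_dprime = rd_fixed(0), p = "constant", c = "constant",
                alpha = rd_fixed(1), f0 = "constant")
  fit <- suppressWarnings(rd_fit(h, m, n_starts = 1))
  K <- fit$K; ne <- fit$n_eff
  expect_equal(fit$AICc,
               -2 * fit$logLik + 2 * K + 2 * K * (K + 1) / (ne - K - 1))
  expect_equal(ne, sum(det))
})

test_that("model averaging renormalizes weights and passes single models through", {
  cfg <- sim_config(
    n_females = 18, n_males = 18, phi_f = 0.9, phi_m = 0.76,
    gamma_dprime = 0.05, gamma_prime = 0.77,
    p_capture = matrix(0.25, 2, 2,
                       dimnames = list(c("F", "M"), c("spring", "fall"))),
    c_recapture = matrix(0.30, 2, 2,
                         dimnames = list(c("F", "M"), c("spring", "fall"))),
    alpha = 0.85, n_pso = 4, sso_per_pso = 5,
    recruits_per_interval = matrix(rep(c(2L, 4L), 3), 3, 2, byrow = TRUE),
    seed = 301)
  truth <- simulate_population(cfg)
  h <- simulated_histories(truth)
  m1 <- rd_model(phi = "sex", p = "constant", c = "constant",
                 alpha = "constant", f0 = "constant")
  m2 <- rd_model(phi = "constant", p = "constant", c = "constant",
                 alpha = "constant", f0 = "constant")
  f1 <- suppressWarnings(rd_fit(h, m1, n_starts = 1))
  f2 <- suppressWarnings(rd_fit(h, m2, n_starts = 1))
  avg <- suppressWarnings(rd_average(list(`Model 1` = f1, `Model 2` = f2),
                                     min_lik = 0, min_weight = 0))
  expect_equal(sum(avg$weights), 1)
  e <- avg$estimates
  w <- avg$weights
  phiF1 <- f1$real$estimate[f1$real$parameter == "phi" & f1$real$level == "F"]
  phiC2 <- f2$real$estimate[f2$real$parameter == "phi"]
  expect_equal(e$estimate[e$parameter == "phi" & e$sex == "F" &
                            e$season == "spring"],
               unname(w["Model 1"] * phiF1 + w["Model 2"] * phiC2),
               tolerance = 1e-10)
  # single-model average passes estimates through
  avg1 <- suppressWarnings(rd_average(list(`Model 1` = f1)))
  eF <- avg1$estimates
  expect_equal(eF$estimate[eF$parameter == "phi" & eF$sex == "F" &
                             eF$season == "fall"], phiF1)
  # selection rule on printed-style ranking tables
  tab <- data.frame(model = paste("Model", 1:6),
                    AICc = c(1779.2, 1779.4, 1780.8, 1781.5, 1782.1, 1783.3),
                    weight = c(0.29, 0.27, 0.13, 0.09, 0.07, 0.04),
                    model_lik = c(1, 0.95, 0.45, 0.32, 0.24, 0.14))
  sel <- select_models(tab)
  expect_equal(sel$model, paste("Model", 1:5))
  expect_equal(attr(sel, "cum_weight"), 0.85)
})

test_that("abundance never drops below the repeat-detection count and ghosts discount singletons", {
  cfg <- recovery_config(77)
  truth <- simulate_population(cfg)
  h <- simulated_histories(truth)
  m <- rd_model(phi = "sex", p = "constant", c = "constant",
                alpha = "constant", f0 = "constant")
  fit <- suppressWarnings(rd_fit(h, m, n_starts = 1, hessian = FALSE))
  ab <- derived_abundance(fit, area_km2 = 3.5)
  cells <- fit$cells
  for (t in seq_len(nrow(ab))) {
    for (g in c("F", "M")) {
      C <- cells$C[cells$group == g & cells$pso == t]
      expect_gte(ab[[paste0("N_", g)]][t], C)
    }
  }
  # expected real singletons strictly below the singleton count when
  # misidentification is estimated
  a_hat <- fit$real$estimate[fit$real$parameter == "alpha"]
  if (a_hat < 0.99) {
    expect_true(all(cells$E_real_singletons <= cells$s_singletons))
    expect_true(any(cells$E_real_singletons < cells$s_singletons))
  }
  expect_equal(ab$sex_ratio, ab$N_M / ab$N_F)
})
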