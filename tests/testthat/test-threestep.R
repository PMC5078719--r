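test_that("modal assignment takes the posterior argmax with a fixed tie rule", {
  expect_equal(modal_assign(rbind(c(0.9, 0.1)))$classes, 1L)
  expect_equal(modal_assign(rbind(c(0.5, 0.5)))$classes, 1L)
  ma <- modal_assign(rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.4, 0.6)))
  expect_equal(ma$classes, c(1L, 2L, 2L))
  expect_equal(ma$proportions, c(1 / 3, 2 / 3))
})

test_that("classification-error matrix matches the weighted cross-tab", {
  p1 <- c(0.9, 0.8, 0.3, 0.2)
  resp <- cbind(p1, 1 - p1)
  em <- classification_error(resp)
  expect_equal(em$q, rbind(c(1.7 / 2.2, 0.5 / 2.2), c(0.3 / 1.8, 1.5 / 1.8)),
               ignore_attr = TRUE)
  expect_equal(round(em$q, 4),
               rbind(c(0.7727, 0.2273), c(0.1667, 0.8333)),
               ignore_attr = TRUE)
  expect_equal(rowSums(em$q), c(1, 1), ignore_attr = TRUE)

  # degenerate posteriors: identity with clamped off-diagonal logits
  hard <- rbind(c(1, 0), c(0, 1), c(1, 0))
  emh <- classification_error(hard)
  expect_equal(emh$q, diag(2), ignore_attr = TRUE)
  expect_gte(emh$logits[1, 1], 14.9)   # P(W=1|C=1)/P(W=2|C=1) at the clamp

  # uniform posteriors: every row equals the modal proportions
  unif <- matrix(0.5, 6, 2)
  emu <- classification_error(unif)
  expect_equal(emu$q[1, ], emu$q[2, ])
  expect_equal(unname(emu$q[1, 1]), 1)  # ties all break to class 1

  expect_error(classification_error(cbind(c(1, 1), c(0, 0))),
               "degenerate class")
})

test_that("step-3 likelihood matches a brute-force contingency oracle", {
  sp <- structural_params(alpha1 = 0.4, alpha2_high = 1.1,
                          alpha2_low = -0.3)
  W1 <- c(1, 1, 2, 2, 1)
  W2 <- c(1, 2, 1, 2, 1)
  # direct multinomial over the 4 cells with identity error
  p1 <- plogis(0.4)
  cell_prob <- c(p1 * plogis(1.1), p1 * (1 - plogis(1.1)),
                 (1 - p1) * plogis(-0.3), (1 - p1) * (1 - plogis(-0.3)))
  idx <- (W1 - 1) * 2 + W2
  expect_equal(step3_loglik(sp, W1, W2), sum(log(cell_prob[idx])),
               tolerance = 1e-10)

  # additivity under duplication
  expect_equal(step3_loglik(sp, rep(W1, 2), rep(W2, 2)),
               2 * step3_loglik(sp, W1, W2), tolerance = 1e-10)

  # with error matrices: mixture over true cells, verified by direct sum
  q <- structure(list(q = rbind(c(0.9, 0.1), c(0.2, 0.8))),
                 class = "error_matrix")
  ll <- step3_loglik(sp, W1, W2, q1 = q, q2 = q)
  brute <- sum(sapply(seq_along(W1), function(i) {
    tot <- 0
    for (g1 in 1:2) for (g2 in 1:2) {
      pg1 <- if (g1 == 1) p1 else 1 - p1
      pg2 <- if (g1 == 1) plogis(1.1) else plogis(-0.3)
      pg2 <- if (g2 == 1) pg2 else 1 - pg2
      tot <- tot + pg1 * pg2 * q$q[g1, W1[i]] * q$q[g2, W2[i]]
    }
    log(tot)
  }))
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("analytic step-3 gradient matches numerical differentiation", {
  set.seed(5)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  W1 <- sample(1:2, n, replace = TRUE)
  W2 <- sample(1:2, n, replace = TRUE)
  q <- structure(list(q = rbind(c(0.85, 0.15), c(0.25, 0.75))),
                 class = "error_matrix")
  par <- c(0.3, 0.5, -0.2, 0.8, -0.4, 0.1, 0.6, -0.3, 0.2)
  obj <- function(v) ltagmm:::step3_objective(v, 2, W1, W2, X, q, q)$value
  g_ana <- ltagmm:::step3_objective(par, 2, W1, W2, X, q, q)$gradient
  g_num <- sapply(seq_along(par), function(j) {
    h <- 1e-6
    e <- numeric(length(par)); e[j] <- h
    (obj(par + e) - obj(par - e)) / (2 * h)
  })
  expect_equal(g_ana, g_num, tolerance = 1e-5)
})

test_that("identity-error null fit reproduces cross-tab proportions", {
  # modal cross-tab with the reference cell counts
  counts <- c(HH = 7093, HL = 0, LH = 336, LL = 374)
  W1 <- rep(c(1, 1, 2, 2), counts)
  W2 <- rep(c(1, 2, 1, 2), counts)
  expect_warning(fit <- fit_step3(W1, W2), "separation")
  expect_equal(unname(fit$transition_matrix["low", "high"]), 336 / 710,
               tolerance = 1e-6)
  expect_equal(unname(fit$transition_matrix["low", "low"]), 374 / 710,
               tolerance = 1e-6)
  expect_equal(round(fit$transition_matrix["low", "high"], 4), 0.4732)
  # the empty high->low cell drives its parameter to the bound
  expect_equal(unname(fit$transition_matrix["high", "high"]), 1,
               tolerance = 1e-6)
  expect_true(fit$clamped[2])
  expect_equal(unname(fit$stage1_proportions["high"]), 7093 / 7803,
               tolerance = 1e-6)
  expect_equal(sum(fit$combination_table$proportion), 1)
  # Table-3-style analogue renders one row per combination
  expect_equal(length(strsplit(render_transition_table(fit), "\n")[[1]]), 5)
})

test_that("maximized likelihood is invariant to the transition reparameterization", {
  set.seed(11)
  n <- 80
  X <- cbind(x = rnorm(n))
  W1 <- sample(1:2, n, replace = TRUE)
  W2 <- sample(1:2, n, replace = TRUE)
  sp <- structural_params(alpha1 = 0.2, beta1 = c(x = 0.5),
                          alpha2_high = 0.7, alpha2_low = -0.1,
                          beta2 = c(x = 0.3), gamma = c(x = -0.6))
  q <- structure(list(q = rbind(c(0.9, 0.1), c(0.15, 0.85))),
                 class = "error_matrix")
  l1 <- step3_loglik(sp, W1, W2, X, q, q)
  # brute-force evaluation of the same likelihood
  eta1 <- 0.2 + X[, 1] * 0.5
  eta2h <- 0.7 + X[, 1] * 0.3
  eta2l <- -0.1 + X[, 1] * (0.3 - 0.6)
  brute <- sum(sapply(seq_len(n), function(i) {
    tot <- 0
    for (g1 in 1:2) for (g2 in 1:2) {
      pg1 <- if (g1 == 1) plogis(eta1[i]) else 1 - plogis(eta1[i])
      e2 <- if (g1 == 1) eta2h[i] else eta2l[i]
      pg2 <- if (g2 == 1) plogis(e2) else 1 - plogis(e2)
      tot <- tot + pg1 * pg2 * q$q[g1, W1[i]] * q$q[g2, W2[i]]
    }
    log(tot)
  }))
  expect_equal(l1, brute, tolerance = 1e-10)
  # relabelling the Stage-1 classes while transforming
  # (alpha1, beta1) -> -(alpha1, beta1), swapping the stage-2 intercepts,
  # beta2 -> beta2 + gamma, gamma -> -gamma and permuting the rows of q1
  # leaves the likelihood unchanged
  sp_swap <- structural_params(alpha1 = -0.2, beta1 = c(x = -0.5),
                               alpha2_high = -0.1, alpha2_low = 0.7,
                               beta2 = c(x = 0.3 - 0.6),
                               gamma = c(x = 0.6))
  q1_swap <- structure(list(q = q$q[2:1, ]), class = "error_matrix")
  expect_equal(step3_loglik(sp_swap, W1, W2, X, q1_swap, q), l1,
               tolerance = 1e-10)
})

test_that("error correction de-attenuates transition estimates", {
  # truth: P(high) = 0.7, transitions high->(0.9,0.1), low->(0.4,0.6);
  # modal classes observed through symmetric 10% error at both stages
  q <- structure(list(q = rbind(c(0.9, 0.1), c(0.1, 0.9))),
                 class = "error_matrix")
  wins_corrected <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 3000
    g1 <- ifelse(runif(n) < 0.7, 1, 2)
    p2 <- ifelse(g1 == 1, 0.9, 0.4)
    g2 <- ifelse(runif(n) < p2, 1, 2)
    flip <- function(g) ifelse(runif(n) < 0.1, 3 - g, g)
    W1 <- flip(g1); W2 <- flip(g2)
    naive <- mean(W2[W1 == 2] == 1)
    fit <- fit_step3(W1, W2, NULL, q, q)
    corrected <- fit$transition_matrix["low", "high"]
    if (abs(corrected - 0.4) < abs(naive - 0.4)) {
      wins_corrected <- wins_corrected + 1
    }
  }
  expect_gte(wins_corrected, 8)
})

test_that("odds ratios exponentiate coefficients per block", {
  sp <- structural_params(alpha1 = 0, beta1 = c(tr = 1.95, pr = -2.77),
                          alpha2_high = 0, alpha2_low = 0,
                          beta2 = c(tr = 0, pr = 0),
                          gamma = c(tr = 0, pr = 0))
  or <- odds_ratios(sp)
  expect_equal(or$odds_ratio[or$term == "tr" & or$block == "stage1"],
               exp(1.95), tolerance = 1e-10)
  expect_equal(round(exp(1.95), 4), 7.0287)
  expect_equal(round(exp(-2.77), 4), 0.0627)
  expect_true(all(or$odds_ratio[or$beta == 0] == 1))
})
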