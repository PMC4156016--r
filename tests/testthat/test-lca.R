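toy_spec <- function(n_items = 2, n_levels = 2) {
  lv <- lapply(seq_len(n_items), function(j)
    paste0("l", seq_len(n_levels)))
  names(lv) <- paste0("item", seq_len(n_items))
  indicator_spec(lv)
}

test_that("log-likelihood matches brute-force mixture enumeration", {
  spec <- toy_spec(2, 2)
  gamma <- c(0.3, 0.7)
  rho <- list(item1 = rbind(c(0.9, 0.1), c(0.2, 0.8)),
              item2 = rbind(c(0.6, 0.4), c(0.3, 0.7)))
  data <- data.frame(item1 = c("l1", "l1", "l2", "l2"),
                     item2 = c("l1", "l2", "l1", "l2"))
  # direct enumeration of sum_c gamma_c prod_j rho for each of the 4 records
  expected <- 0
  for (i in seq_len(4)) {
    y1 <- match(data$item1[i], c("l1", "l2"))
    y2 <- match(data$item2[i], c("l1", "l2"))
    expected <- expected +
      log(sum(gamma * rho$item1[, y1] * rho$item2[, y2]))
  }
  expect_equal(lca_log_likelihood(data, toy_model(gamma, rho), spec),
               expected, tolerance = 1e-12)
})

test_that("one-class log-likelihood has the closed independence form", {
  spec <- toy_spec(3, 2)
  set.seed(2)
  data <- as.data.frame(lapply(spec$levels, function(lv)
    sample(lv, 50, replace = TRUE)))
  marg <- lapply(spec$items, function(it)
    matrix(prop.table(table(factor(data[[it]], spec$levels[[it]]))),
           nrow = 1))
  names(marg) <- spec$items
  expected <- sum(vapply(spec$items, function(it) {
    n_k <- table(factor(data[[it]], spec$levels[[it]]))
    sum(n_k * log(n_k / 50))
  }, numeric(1)))
  expect_equal(lca_log_likelihood(data, toy_model(1, marg), spec),
               expected, tolerance = 1e-10)
  # the K = 1 fit lands on exactly these marginals in one step
  fit1 <- lca_fit(data, 1, spec)
  for (it in spec$items)
    expect_equal(unname(fit1$rho[[it]]), unname(marg[[it]]),
                 tolerance = 1e-9)
  expect_equal(fit1$log_likelihood, expected, tolerance = 1e-10)
})

test_that("log-likelihood is invariant to class relabeling", {
  spec <- toy_spec(2, 3)
  gamma <- c(0.2, 0.5, 0.3)
  set.seed(8)
  rho <- lapply(spec$levels, function(lv) {
    m <- matrix(rgamma(9, 1), 3)
    m / rowSums(m)
  })
  data <- simulate_lca(gamma, rho, spec, 40, seed = 3)
  ll <- lca_log_likelihood(data, toy_model(gamma, rho), spec)
  perm <- c(3, 1, 2)
  rho_p <- lapply(rho, function(m) m[perm, , drop = FALSE])
  expect_equal(lca_log_likelihood(data, toy_model(gamma[perm], rho_p), spec),
               ll, tolerance = 1e-12)
})

test_that("EM recovers a well-separated two-class model at n = 2000", {
  spec <- toy_spec(5, 2)
  gamma <- c(0.6, 0.4)
  rho <- lapply(spec$levels, function(lv)
    rbind(c(0.85, 0.15), c(0.15, 0.85)))
  data <- simulate_lca(gamma, rho, spec, 2000, seed = 21)
  fit <- lca_fit(data, 2, spec, fit_config(n_starts = 10, seed = 4))
  err <- recovery_errors(fit, gamma, rho)
  expect_lte(err$gamma, 0.03)
  expect_lte(err$rho, 0.05)
  expect_em_invariants(fit)
})

test_that("the maximized log-likelihood does not depend on item order", {
  spec <- toy_spec(4, 2)
  gamma <- c(0.55, 0.45)
  rho <- lapply(spec$levels, function(lv)
    rbind(c(0.9, 0.1), c(0.2, 0.8)))
  data <- simulate_lca(gamma, rho, spec, 500, seed = 6)
  fit_a <- lca_fit(data, 2, spec, fit_config(n_starts = 10, seed = 5))
  rev_items <- rev(spec$items)
  spec_rev <- indicator_spec(spec$levels[rev_items])
  fit_b <- lca_fit(data[rev_items], 2, spec_rev,
                   fit_config(n_starts = 10, seed = 5))
  expect_equal(fit_a$log_likelihood, fit_b$log_likelihood, tolerance = 1e-6)
})

test_that("identical data and configuration give bitwise-identical fits", {
  spec <- toy_spec(3, 3)
  set.seed(10)
  rho <- lapply(spec$levels, function(lv) {
    m <- matrix(rgamma(6, 1), 2)
    m / rowSums(m)
  })
  data <- simulate_lca(c(0.5, 0.5), rho, spec, 300, seed = 11)
  f1 <- lca_fit(data, 2, spec, fit_config(n_starts = 5, seed = 99))
  f2 <- lca_fit(data, 2, spec, fit_config(n_starts = 5, seed = 99))
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$rho, f2$rho)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("G2 is zero for a saturating model and matches the classical LR statistic", {
  spec <- toy_spec(2, 2)
  # uniform 2x2 table: the one-class (independence) model fits exactly
  data <- data.frame(item1 = rep(c("l1", "l1", "l2", "l2"), 5),
                     item2 = rep(c("l1", "l2", "l1", "l2"), 5))
  fit1 <- lca_fit(data, 1, spec)
  st <- compute_fit_stats(fit1, data, spec)
  expect_equal(st$G2, 0, tolerance = 1e-8)

  # dependent 2x2 table: K = 1 G2 equals the classical likelihood-ratio
  # independence statistic computed by direct cell enumeration
  counts <- matrix(c(30, 10, 5, 25), 2, dimnames = NULL)
  data2 <- data.frame(
    item1 = rep(rep(c("l1", "l2"), each = 2), times = c(30, 10, 5, 25)),
    item2 = rep(rep(c("l1", "l2"), times = 2), times = c(30, 10, 5, 25)))
  n <- sum(counts)
  expected_lr <- 0
  for (r in 1:2) for (cc in 1:2) {
    e <- sum(counts[r, ]) * sum(counts[, cc]) / n
    expected_lr <- expected_lr + 2 * counts[r, cc] * log(counts[r, cc] / e)
  }
  fit2 <- lca_fit(data2, 1, spec)
  st2 <- compute_fit_stats(fit2, data2, spec)
  expect_equal(st2$G2, expected_lr, tolerance = 1e-6)
})

test_that("parameter and df accounting matches the closed formulas", {
  espec <- engagement_spec()
  ep <- engagement_params()
  data <- simulate_lca(ep$gamma, ep$rho, espec, 50, seed = 14)
  st <- compute_fit_stats(toy_model(ep$gamma, ep$rho), data, espec)
  expect_equal(st$n_params, 5L + 6L * 16L)           # (K-1) + K sum(k_j - 1)
  expect_equal(st$df, (4^2 * 3^5 - 1L) - 101L)       # 3786
  expect_false(st$df_unreliable)
  expect_equal(st$AIC, st$G2 + 2 * st$n_params)
  expect_equal(st$BIC, st$G2 + log(50) * st$n_params)
})

test_that("model selection sweeps report consistent rows and pick K by BIC", {
  spec <- toy_spec(4, 2)
  gamma <- c(0.4, 0.35, 0.25)
  set.seed(15)
  rho <- lapply(spec$levels, function(lv) {
    m <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.5, 0.5))
    m
  })
  data <- simulate_lca(gamma, rho, spec, 800, seed = 16)
  sw <- select_model(data, spec, 1:3, fit_config(n_starts = 8, seed = 17))
  expect_equal(sw$table$K, 1:3)
  # the K = 1 row must agree with a direct one-class fit
  st1 <- compute_fit_stats(lca_fit(data, 1, spec), data, spec)
  expect_equal(sw$table$G2[1], st1$G2, tolerance = 1e-8)
  expect_equal(sw$selected_k, sw$table$K[which.min(sw$table$BIC)])
  # maximized log-likelihood is non-decreasing in K
  expect_true(all(diff(sw$table$log_likelihood) > -1e-6))
  # degenerate sweep
  sw1 <- select_model(data, spec, 1, fit_config(n_starts = 2, seed = 1))
  expect_equal(sw1$selected_k, 1L)
})

test_that("posteriors follow Bayes' rule and modal shares approach gamma", {
  spec <- indicator_spec(list(item1 = c("l1", "l2")))
  model <- toy_model(c(0.5, 0.5),
                     list(item1 = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  pc <- posterior_classify(model, data.frame(item1 = "l1"), spec)
  expect_equal(unname(pc$posterior[1, 1]), 0.45 / 0.55, tolerance = 1e-12)
  expect_equal(rowSums(pc$posterior), 1, ignore_attr = TRUE)

  # K = 1: every posterior is 1
  spec3 <- toy_spec(2, 2)
  d <- data.frame(item1 = c("l1", "l2"), item2 = c("l2", "l1"))
  fit1 <- lca_fit(d, 1, spec3)
  expect_true(all(posterior_classify(fit1, d)$posterior == 1))

  # modal shares on a large well-separated sample approach gamma
  spec5 <- toy_spec(5, 2)
  gamma <- c(0.65, 0.35)
  rho <- lapply(spec5$levels, function(lv)
    rbind(c(0.9, 0.1), c(0.1, 0.9)))
  data <- simulate_lca(gamma, rho, spec5, 10000, seed = 18)
  shares <- prop.table(table(
    posterior_classify(toy_model(gamma, rho), data, spec5)$modal_class))
  expect_lte(max(abs(as.numeric(shares) - gamma)), 0.02)
})

test_that("class alignment undoes label switching", {
  ep <- engagement_params()
  ref <- toy_model(ep$gamma, ep$rho)
  expect_equal(unname(align_classes(ref, ref)), 1:6, ignore_attr = TRUE)

  perm <- c(4, 1, 6, 2, 5, 3)
  cand <- toy_model(ep$gamma[perm],
                    lapply(ep$rho, function(m) m[perm, , drop = FALSE]))
  back <- align_classes(ref, cand)
  expect_equal(as.integer(back), order(perm))
  aligned <- permute_classes(cand, back)
  expect_equal(unname(aligned$gamma), unname(ep$gamma))

  # noisy refit of a well-separated 4-class model: alignment recovers the
  # generator labels
  spec4 <- indicator_spec(lapply(
    stats::setNames(paste0("item", 1:4), paste0("item", 1:4)),
    function(i) c("a", "b", "c")))
  gam4 <- c(0.35, 0.3, 0.2, 0.15)
  fav <- rbind(c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3), c(1, 2, 3, 1))
  rho4 <- lapply(seq_len(4), function(j) {
    m <- matrix(0.05, 4, 3)
    for (c4 in 1:4) m[c4, fav[c4, j]] <- 0.9
    m / rowSums(m)
  })
  names(rho4) <- spec4$items
  data <- simulate_lca(gam4, rho4, spec4, 3000, seed = 19)
  fit <- lca_fit(data, 4, spec4, fit_config(n_starts = 10, seed = 20))
  err <- recovery_errors(fit, gam4, rho4)
  expect_lte(err$gamma, 0.05)
  # independent oracle: the fitted class that most often captures each true
  # class must be exactly the class the L1 alignment pairs with it
  modal <- posterior_classify(fit, data, spec4)$modal_class
  truth_cls <- attr(data, "class_idx")
  oracle_perm <- vapply(1:4, function(c4) {
    as.integer(names(which.max(table(modal[truth_cls == c4]))))
  }, integer(1))
  perm <- align_classes(toy_model(gam4, rho4), fit)
  expect_equal(as.integer(perm), oracle_perm)
  expect_error(align_classes(ref, toy_model(gam4, rho4)),
               "different numbers")
})

test_that("mismatched model and spec dimensions are rejected", {
  spec <- toy_spec(2, 2)
  bad <- toy_model(c(0.5, 0.5),
                   list(item1 = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  d <- data.frame(item1 = "l1", item2 = "l2")
  expect_error(lca_log_likelihood(d, bad, spec), "match")
  expect_error(lca_fit(d, 5, spec), "at least K")
  expect_error(lca_log_likelihood(
    data.frame(item1 = "zzz", item2 = "l1"),
    toy_model(1, list(item1 = matrix(c(0.5, 0.5), 1),
                      item2 = matrix(c(0.5, 0.5), 1))), spec),
    "undeclared")
})
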