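test_that("univariate Cox matches grid-search partial-likelihood oracles", {
  # 4 subjects, all events, binary covariate alternating with event order
  cl <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 1)
  x <- c(1, 0, 1, 0)
  fit <- cox_univariate(x, cl)
  expect_true(fit$converged)
  expect_equal(fit$beta, grid_cox_beta(cl$time, cl$event, x),
               tolerance = 1e-4)
  # a covariate perfectly aligned with the event order has a monotone
  # partial likelihood: both the fit and the grid oracle run to the bound
  expect_warning(sep <- cox_univariate(c(1, 1, 0, 0), cl), "capped")
  expect_false(sep$converged)
  # assorted <= 6-subject fixtures with censoring and ties
  fixtures <- list(
    list(time = c(2, 3, 3, 5, 7, 9), event = c(1, 1, 0, 1, 0, 1),
         x = c(0.5, -1, 2, 0, 1, -0.5)),
    list(time = c(1, 1, 2, 4, 6), event = c(1, 1, 1, 0, 1),
         x = c(2, 1, 0, -1, -2)),
    list(time = c(4, 2, 6, 8), event = c(1, 1, 1, 0),
         x = c(0, 1, 0.5, 1.5)))
  for (f in fixtures) {
    cl <- data.frame(sample_id = seq_along(f$time), time = f$time,
                     event = f$event)
    fit <- cox_univariate(f$x, cl)
    expect_equal(fit$beta, grid_cox_beta(f$time, f$event, f$x),
                 tolerance = 1e-4)
  }
})

test_that("degenerate Cox inputs are flagged, not propagated", {
  cl <- data.frame(sample_id = paste0("s", 1:4), time = 1:4, event = 1)
  fit <- cox_univariate(rep(2, 4), cl)
  expect_equal(fit$beta, 0)
  expect_false(fit$converged)
  expect_error(cox_univariate(c(1, 2, 3, 4),
                              transform(cl, event = 0)), "no events")
  # perfect separation: covariate orders exactly with survival time
  cl2 <- data.frame(sample_id = paste0("s", 1:6), time = 1:6, event = 1)
  expect_warning(fit2 <- cox_univariate(c(6, 5, 4, 3, 2, 1), cl2),
                 "monotone|capped")
  expect_false(fit2$converged)
  expect_lte(abs(fit2$beta), 15)
})

test_that("planted Cox effect is recovered within 3 standard errors", {
  hits <- replicate(30, {
    s <- generate_study(synth_config(
      n_tumor = 200L, n_normal = 3L, n_mirna = 10L, n_lncrna = 5L,
      n_mrna = 20L, n_prognostic = 2L, beta_prognostic = 0.7,
      n_true_edges = 0L, n_triplets = 0L, seed = sample.int(1e6, 1)))
    l2 <- log2_standardize(s$expr$mRNA)
    pf <- names(s$truth$prognostic)
    pf <- pf[pf %in% rownames(l2)]
    if (!length(pf)) return(NA)
    f <- cox_univariate(as.numeric(l2[pf[1], s$clinical$sample_id]),
                        s$clinical, pf[1])
    abs(f$beta - 0.7) <= 3 * f$se
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("risk scores are dot products with mean-cutoff stratification", {
  samples <- paste0("s", 1:4)
  expr <- toy_expr(c(1, 2, 3, 4,
                     0, 1, 0, 1,
                     2, 2, 2, 2), c("f1", "f2", "f3"), samples, "mRNA")
  mod <- risk_model(c("f1", "f2", "f3"), c(0.5, -1, 0.25))
  st <- risk_score(mod, expr)
  hand <- 0.5 * c(1, 2, 3, 4) - 1 * c(0, 1, 0, 1) + 0.25 * 2
  expect_equal(st$score, hand)
  expect_equal(attr(st, "cutoff"), mean(hand))
  expect_identical(as.character(st$group), ifelse(hand > mean(hand),
                                                  "high", "low"))
  # all-zero coefficients: degenerate, everyone low
  mod0 <- risk_model("f1", 0)
  expect_warning(st0 <- risk_score(mod0, expr), "degenerate")
  expect_true(all(st0$group == "low"))
  expect_error(risk_score(risk_model("missing", 1), expr), "missing")
  # single feature with beta 1: score equals that feature's expression
  st1 <- risk_score(risk_model("f1", 1), expr)
  expect_equal(st1$score, c(1, 2, 3, 4))
})

test_that("group assignment is invariant to adding a constant to scores", {
  set.seed(6)
  sc <- rnorm(20)
  g1 <- ifelse(sc > mean(sc), "high", "low")
  g2 <- ifelse(sc + 5 > mean(sc + 5), "high", "low")
  expect_identical(g1, g2)
})

test_that("log-rank matches a hand-computed 10-subject event table", {
  # groups A/B, times and events fixed; oracle computed from the 2x2
  # per-event-time observed/expected decomposition
  time <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10)
  event <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 5)
  cl <- data.frame(sample_id = paste0("s", 1:10), time = time, event = event)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == "A")
    d1 <- sum(event == 1 & time == t & grp == "A")
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2_hand <- o_minus_e^2 / v
  km <- km_logrank(cl, grp)
  expect_equal(km$logrank_chi2, chi2_hand, tolerance = 1e-10)
  expect_equal(km$logrank_p, pchisq(chi2_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("KM curves equal the empirical survival function without censoring", {
  time <- c(1, 2, 3, 4, 5, 6)
  cl <- data.frame(sample_id = paste0("s", 1:6), time = time, event = 1)
  grp <- rep(c("A", "B"), each = 3)
  km <- km_logrank(cl, grp)
  a <- km$curves[km$curves$group == "A", ]
  expect_equal(a$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(km$curves$surv[km$curves$group == "B"]) <= 0))
})

test_that("log-rank is symmetric in group labels and handles no events", {
  time <- c(2, 4, 6, 8, 3, 5, 7, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  cl <- data.frame(sample_id = paste0("s", 1:8), time = time, event = event)
  g <- rep(c("A", "B"), each = 4)
  k1 <- km_logrank(cl, g)
  k2 <- km_logrank(cl, rev(g))
  expect_equal(k1$logrank_chi2, k2$logrank_chi2, tolerance = 1e-10)
  cl0 <- transform(cl, event = 0)
  expect_warning(k0 <- km_logrank(cl0, g), "no events")
  expect_equal(k0$logrank_p, 1)
  # identical event patterns in both groups: chi2 0, p 1
  clid <- data.frame(sample_id = paste0("s", 1:8),
                     time = rep(c(1, 2, 3, 4), 2), event = 1)
  kid <- km_logrank(clid, g)
  expect_equal(kid$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(kid$logrank_p, 1)
})

test_that("AUC equals the exhaustive pairwise comparison count", {
  sc <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.1)
  lab <- c(1, 1, 0, 1, 0, 0)
  # brute force over all positive/negative pairs, ties count 1/2
  pos <- which(lab == 1); neg <- which(lab == 0)
  cmp <- outer(sc[pos], sc[neg], function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(sc, lab), mean(cmp))
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both outcome classes")
})

test_that("AUC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(10)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})
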