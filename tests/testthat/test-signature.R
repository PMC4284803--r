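toy_cohort <- function(n = 6, delta = 2, sigma = 0.5, seed = 61,
                       markers = c("m1", "m2")) {
  set.seed(seed)
  grid <- tidyr::expand_grid(patient = sprintf("P%02d", 1:n),
                             marker = markers,
                             tissue = c("normal", "tumour"))
  grid$reference_ct <- 20
  grid$ct <- 20 + 5 + rnorm(nrow(grid), 0, sigma) +
    ifelse(grid$tissue == "tumour", delta, 0)
  delta_ct(grid)
}

test_that("delta-Ct arithmetic and the qPCR fold-change identity hold", {
  x <- tibble::tibble(patient = "P1", tissue = c("tumour", "normal"),
                      marker = "m", ct = c(30, 25), reference_ct = c(20, 20))
  d <- delta_ct(x)
  expect_equal(d$delta_ct, c(10, 5))
  ddct <- d$delta_ct[1] - d$delta_ct[2]
  expect_equal(2^-(-1), 2)  # fold change identity at ddCt = -1
  expect_equal(2^-ddct, 2^-5)
  eq <- delta_ct(dplyr::mutate(x, ct = reference_ct))
  expect_equal(eq$delta_ct, c(0, 0))
  # missing Ct is flagged, not zeroed
  miss <- delta_ct(dplyr::mutate(x, ct = c(NA, 25)))
  expect_true(miss$missing[1])
  expect_true(is.na(miss$delta_ct[1]))
})

test_that("the paired test handles identical and degenerate cohorts", {
  co <- toy_cohort(delta = 0, sigma = 0)
  pd <- paired_differential(co)
  expect_equal(pd$mean_difference, c(0, 0))
  expect_equal(pd$p_value, c(1, 1))
  expect_true(all(pd$degenerate))
  co2 <- toy_cohort(delta = 3, sigma = 0)
  pd2 <- paired_differential(co2)
  expect_true(all(pd2$degenerate))
  expect_true(all(pd2$p_value < 1e-300))
  expect_true(all(pd2$significant))
  co3 <- toy_cohort(n = 35, delta = 2, sigma = 1)
  pd3 <- paired_differential(co3)
  expect_true(all(pd3$significant))
  expect_false(any(pd3$degenerate))
})

test_that("ROC/AUC covers the canonical small cases", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  ties <- roc_auc(rep(5, 8), rep(c(0, 1), 4))
  expect_equal(ties$auc, 0.5)
  # positives {2, 4} vs negatives {1, 3}: 3 of 4 pairs concordant
  quad <- roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(quad$auc, 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # curve endpoints
  expect_equal(perfect$curve$sensitivity[1], 0)
  expect_equal(utils::tail(perfect$curve$sensitivity, 1), 1)
  expect_equal(utils::tail(perfect$curve$one_minus_specificity, 1), 1)
})

test_that("trapezoid AUC equals the tie-corrected concordance everywhere", {
  set.seed(62)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(1:8, n, TRUE)  # heavy ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, bf_auc_concordance(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  for (i in 1:5) {
    scores <- rnorm(40)
    labels <- sample(0:1, 40, TRUE, prob = c(0.4, 0.6))
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-10)
  }
})

test_that("signature selection uses a strict AUC cutoff", {
  pm <- tibble::tibble(marker = c("a", "b", "c"), auc = c(0.9, 0.65, 0.72))
  expect_equal(select_signature(pm, 0.7), c("a", "c"))
  pm2 <- tibble::tibble(marker = "x", auc = 0.70)
  expect_warning(sel <- select_signature(pm2, 0.7), "exceeds")
  expect_equal(length(sel), 0)
  expect_warning(all_back <- select_signature(pm2, 0.7, fallback_all = TRUE))
  expect_equal(all_back, "x")
})

test_that("IRLS logistic regression matches glm and a direct Newton solver", {
  set.seed(64)
  n <- 400
  x <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- -0.5 + 0.9 * x[, 1] - 1.2 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  ref <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  expect_equal(unname(c(fit$intercept, fit$weights)),
               unname(ref$coefficients), tolerance = 1e-6)
  newton <- bf_newton_logistic(x, y)
  expect_equal(unname(c(fit$intercept, fit$weights)), unname(newton),
               tolerance = 1e-6)
  # standard errors match glm's
  se_glm <- sqrt(diag(chol2inv(chol(t(cbind(1, x)) %*%
    (cbind(1, x) * ref$weights)))))
  expect_equal(unname(fit$std_errors), se_glm, tolerance = 1e-5)
})

test_that("degenerate designs: constant features, constant labels, separation", {
  y <- rep(c(0, 1), c(30, 10))
  fit <- fit_logistic(matrix(5, 40, 1, dimnames = list(NULL, "z")), y)
  expect_equal(unname(fit$weights), 0)
  expect_equal(fit$intercept, qlogis(0.25), tolerance = 1e-8)
  expect_error(fit_logistic(matrix(rnorm(10)), rep(1, 10)), "constant")
  sep <- fit_logistic(matrix(c(1:5, 11:15), ncol = 1,
                             dimnames = list(NULL, "x")),
                      rep(c(0, 1), each = 5))
  expect_true(sep$separation)
  expect_false(sep$converged)
  expect_true(all(is.finite(c(sep$intercept, sep$weights))))
  # ridge keeps a separable fit finite and converged
  ridged <- fit_logistic(matrix(c(1:5, 11:15), ncol = 1,
                                dimnames = list(NULL, "x")),
                         rep(c(0, 1), each = 5), ridge = 0.1)
  expect_true(ridged$converged)
})

test_that("broom-style accessors expose fits and signatures as tibbles", {
  set.seed(65)
  x <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(50, 1, 0.5)
  fit <- fit_logistic(x, y)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "a", "b"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_true(all(c("logLik", "converged") %in% names(gl)))
})

test_that("cross-validated signature is a seeded, patient-grouped partition", {
  co <- toy_cohort(n = 30, delta = 1.5, sigma = 1, markers = paste0("m", 1:3))
  sig <- crossval_signature(co, k = 5, seed = 99)
  preds <- sig$predictions
  # every sample scored exactly once
  expect_equal(nrow(preds), 60)
  expect_true(all(table(preds$patient, preds$fold) %in% c(0, 2)))
  # both tissues of a patient share a fold
  by_pat <- tapply(preds$fold, preds$patient, function(f) length(unique(f)))
  expect_true(all(by_pat == 1))
  # determinism
  sig2 <- crossval_signature(co, k = 5, seed = 99)
  expect_equal(sig$predictions, sig2$predictions)
  expect_equal(sig$pooled_auc, sig2$pooled_auc)
  sig3 <- crossval_signature(co, k = 5, seed = 100)
  expect_false(identical(sig$predictions$fold, sig3$predictions$fold))
  expect_error(crossval_signature(co, k = 50, seed = 1), "exceeds")
  gl <- glance(sig)
  expect_equal(gl$k, 5)
  expect_equal(gl$seed, 99)
})

test_that("uninformative markers cross-validate to chance-level AUC", {
  co <- toy_cohort(n = 250, delta = 0, sigma = 1, seed = 66,
                   markers = paste0("m", 1:2))
  sig <- suppressWarnings(crossval_signature(co, k = 10, seed = 7))
  expect_lt(abs(sig$pooled_auc - 0.5), 0.06)
})

test_that("hierarchical clustering orders markers and patients sensibly", {
  set.seed(67)
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("mk", 1:4), paste0("P", 1:10)))
  m[, 10] <- m[, 1]  # identical patients
  cl <- cluster_samples(m)
  first_merge <- cl$patient_hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 10))
  expect_setequal(cl$patient_order, 1:10)
  expect_setequal(cl$marker_order, 1:4)
  # the distances behind the tree equal a direct recomputation
  d <- as.matrix(stats::dist(t(m)))
  d2 <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    d2[i, j] <- sqrt(sum((m[, i] - m[, j])^2))
  }
  expect_equal(unname(d), d2, tolerance = 1e-12)
  # permutation leaves the leaf set unchanged
  perm <- sample(10)
  cl2 <- cluster_samples(m[, perm])
  expect_setequal(cl2$patient_order, 1:10)
  expect_error(cluster_samples(matrix(c(1, NA), 1, 2)), "missing")
  expect_equal(cluster_samples(m[1, , drop = FALSE])$marker_order, 1L)
})
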