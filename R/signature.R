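# Tumour/normal qPCR biomarker signature: delta-Ct, paired testing,
# per-marker ROC/AUC, AUC-threshold selection, k-fold CV logistic regression,
# sample clustering.

#' Read a paired-cohort qPCR Ct table
#'
#' @param path TSV with columns `patient`, `tissue` (`tumour`/`normal`),
#'   `marker`, `ct`, `reference_ct`.
#' @return Tibble with those columns.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("patient", "tissue", "marker", "ct", "reference_ct")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) abort(sprintf("Ct table lacks column(s): %s",
                                      paste(miss, collapse = ", ")))
  bad <- setdiff(unique(x$tissue), c("tumour", "normal"))
  if (length(bad) > 0) abort(sprintf("unknown tissue label(s): %s",
                                     paste(bad, collapse = ", ")))
  x
}

#' Delta-Ct values
#'
#' `delta_ct = ct - reference_ct` (target minus reference gene, e.g. GAPDH).
#' Higher delta-Ct means lower expression. Missing Ct values propagate as
#' `NA` and are flagged, never silently zeroed.
#'
#' @param ct_table Tibble from [read_ct_table()].
#' @return Input with added `delta_ct` and logical `missing` columns.
#' @export
delta_ct <- function(ct_table) {
  ct_table %>%
    mutate(delta_ct = .data$ct - .data$reference_ct,
           missing = !is.finite(.data$ct) | !is.finite(.data$reference_ct))
}

#' Wide per-patient delta-Ct matrix for one tissue
#'
#' @param cohort Output of [delta_ct()].
#' @param tissue `"tumour"` or `"normal"`.
#' @return Tibble with `patient` and one column per marker.
#' @export
delta_ct_matrix <- function(cohort, tissue) {
  cohort %>%
    filter(.data$tissue == !!tissue) %>%
    select("patient", "marker", "delta_ct") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "delta_ct") %>%
    arrange(.data$patient)
}

#' Paired tumour-normal differential test per marker
#'
#' Two-tailed paired Student's t-test on per-patient
#' `delta_ct(tumour) - delta_ct(normal)` differences, one test per marker.
#' Positive mean difference means lower expression in tumours. Degenerate
#' zero-variance differences are handled explicitly: all-zero differences
#' give p = 1; identical nonzero differences are reported below the machine
#' floor with `degenerate = TRUE`.
#'
#' @param cohort Output of [delta_ct()] over a paired cohort.
#' @param alpha Significance level for the `significant` flag (default 0.01).
#' @return Tibble with `marker`, `n_pairs`, `mean_difference`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
paired_differential <- function(cohort, alpha = 0.01) {
  paired <- cohort %>%
    filter(!.data$missing) %>%
    select("patient", "marker", "tissue", "delta_ct") %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "delta_ct") %>%
    filter(is.finite(.data$tumour), is.finite(.data$normal))
  split(paired, paired$marker) %>%
    purrr::imap(function(g, mk) {
      d <- g$tumour - g$normal
      if (length(d) < 2) abort("paired test needs at least 2 complete pairs")
      if (stats::sd(d) == 0) {
        p <- if (mean(d) == 0) 1 else .Machine$double.xmin
        tibble(marker = mk, n_pairs = length(d), mean_difference = mean(d),
               p_value = p, degenerate = TRUE)
      } else {
        tt <- stats::t.test(g$tumour, g$normal, paired = TRUE)
        tibble(marker = mk, n_pairs = length(d),
               mean_difference = unname(tt$estimate),
               p_value = tt$p.value, degenerate = FALSE)
      }
    }) %>%
    bind_rows() %>%
    mutate(significant = .data$p_value < alpha) %>%
    select("marker", "n_pairs", "mean_difference", "p_value", "significant",
           "degenerate")
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC curve over all distinct score thresholds (higher score =
#' more positive-like; here, higher delta-Ct = more tumour-like) and the
#' trapezoidal area under it. Tied scores cross their threshold together,
#' producing a diagonal segment, so the trapezoid equals the tie-corrected
#' concordance statistic (concordant + ties/2) / (n1 * n0).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive class, e.g. tumour).
#' @return Object of class `"lncsig_roc"`: list with `curve` (tibble
#'   `threshold`, `sensitivity`, `one_minus_specificity`), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  curve <- tibble(threshold = c(Inf, thr),
                  sensitivity = c(0, sens),
                  one_minus_specificity = c(0, fpr))
  auc <- sum(diff(curve$one_minus_specificity) *
               (utils::head(curve$sensitivity, -1) +
                  utils::tail(curve$sensitivity, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "lncsig_roc")
}

#' @export
print.lncsig_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy lncsig_roc
#' @export
tidy.lncsig_roc <- function(x, ...) x$curve

#' @method glance lncsig_roc
#' @export
glance.lncsig_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot lncsig_roc
#' @export
autoplot.lncsig_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$one_minus_specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Per-marker ROC analysis of a paired cohort
#'
#' For each marker, scores are the delta-Ct values of all samples (both
#' tissues) and the positive class is tumour.
#'
#' @param cohort Output of [delta_ct()].
#' @return Tibble `marker`, `auc`, `n_pos`, `n_neg`, in input marker order.
#' @export
marker_roc <- function(cohort) {
  markers <- unique(cohort$marker)
  purrr::map(markers, function(mk) {
    x <- cohort %>% filter(.data$marker == mk, !.data$missing)
    r <- roc_auc(x$delta_ct, x$tissue == "tumour")
    tibble(marker = mk, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)
  }) %>% bind_rows()
}

#' Select signature markers by AUC threshold
#'
#' Markers with AUC strictly greater than `cutoff`, in input order. An empty
#' selection triggers a warning; with `fallback_all = TRUE` the full marker
#' set is returned instead so downstream fitting can proceed.
#'
#' @param per_marker_auc Tibble with `marker` and `auc` ([marker_roc()]).
#' @param cutoff AUC cutoff (default 0.7; strict inequality).
#' @param fallback_all Return all markers when none pass (default FALSE).
#' @return Character vector of selected marker names.
#' @export
select_signature <- function(per_marker_auc, cutoff = 0.7,
                             fallback_all = FALSE) {
  if (nrow(per_marker_auc) == 0) abort("no markers evaluated")
  sel <- per_marker_auc$marker[per_marker_auc$auc > cutoff]
  if (length(sel) == 0) {
    warn(sprintf("no marker exceeds AUC %.2f", cutoff))
    if (fallback_all) return(per_marker_auc$marker)
  }
  sel
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit; convergence when the log-likelihood
#' change falls below `tol`. Quasi-complete separation is detected when any
#' coefficient magnitude exceeds `weight_cap`: iteration stops, the capped
#' model is returned with `converged = FALSE` and `separation = TRUE`.
#' An optional ridge penalty is available for separable data.
#'
#' @param x Numeric feature matrix (or data frame), one column per feature.
#' @param y Binary response (0/1); must contain both classes.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param weight_cap Coefficient magnitude triggering the separation flag
#'   (default 30).
#' @param ridge Ridge penalty lambda (default 0 = plain ML).
#' @return Object of class `"lncsig_logistic"`: list with `intercept`,
#'   `weights` (named), `std_errors`, `log_lik`, `iterations`, `converged`,
#'   `separation`.
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol = 1e-8, weight_cap = 30,
                         ridge = 0) {
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("response is constant; both classes required")
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  # zero-variance features carry no information: weight 0, fit the rest
  sdx <- apply(x, 2, stats::sd)
  if (any(sdx == 0)) {
    keep <- sdx > 0
    sub <- fit_logistic(x[, keep, drop = FALSE], y, max_iter = max_iter,
                        tol = tol, weight_cap = weight_cap, ridge = ridge)
    w <- setNames(rep(0, ncol(x)), colnames(x))
    se <- setNames(rep(NA_real_, ncol(x) + 1L),
                   c("(Intercept)", colnames(x)))
    w[keep] <- sub$weights
    se[c("(Intercept)", colnames(x)[keep])] <- sub$std_errors
    sub$weights <- w
    sub$std_errors <- se
    return(sub)
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1L)), nrow = p)
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + pen, XtW %*% z))
    if (any(abs(beta) > weight_cap)) {
      separation <- TRUE
      beta <- pmin(pmax(beta, -weight_cap), weight_cap)
      break
    }
    ll <- sum(y * log(stats::plogis(drop(X %*% beta))) +
                (1 - y) * log(1 - stats::plogis(drop(X %*% beta))))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X + pen
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  structure(list(intercept = unname(beta[1]),
                 weights = setNames(beta[-1], colnames(x)),
                 std_errors = setNames(se, colnames(X)),
                 log_lik = ll_old, iterations = iter,
                 converged = converged, separation = separation),
            class = "lncsig_logistic")
}

#' Predict probabilities from a fitted logistic model
#'
#' @param object A `"lncsig_logistic"` fit.
#' @param newdata Feature matrix with the model's columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.lncsig_logistic <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, names(object$weights), drop = FALSE]
  stats::plogis(drop(x %*% object$weights) + object$intercept)
}

#' @export
print.lncsig_logistic <- function(x, ...) {
  cat(sprintf("Logistic fit: %d feature(s), logLik %.3f, %d iteration(s)%s\n",
              length(x$weights), x$log_lik, x$iterations,
              if (x$separation) " [separation detected]" else ""))
  print(c(`(Intercept)` = unname(x$intercept), x$weights))
  invisible(x)
}

#' @method tidy lncsig_logistic
#' @export
tidy.lncsig_logistic <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$weights)),
         estimate = c(unname(x$intercept), unname(x$weights)),
         std.error = unname(x$std_errors))
}

#' @method glance lncsig_logistic
#' @export
glance.lncsig_logistic <- function(x, ...) {
  tibble(logLik = x$log_lik, iterations = x$iterations,
         converged = x$converged, separation = x$separation)
}

# deterministic patient-grouped stratified folds: both tissues of a patient
# share the patient's fold
.make_folds <- function(patients, k, seed) {
  uq <- sort(unique(patients))
  if (length(uq) < k) abort("k exceeds the number of patients")
  set.seed(seed)
  shuffled <- sample(uq)
  fold_of <- setNames(rep(seq_len(k), length.out = length(uq)), shuffled)
  unname(fold_of[as.character(patients)])
}

#' Cross-validated multi-marker signature evaluation
#'
#' Runs the full signature procedure on a paired cohort: per-marker ROC,
#' AUC-threshold selection, then k-fold cross-validated logistic regression
#' over the selected markers' delta-Ct values. Folds are deterministic given
#' the seed, stratified by construction (each patient contributes one tumour
#' and one normal sample) and patient-grouped (both samples of a patient sit
#' in the same fold). Out-of-fold predicted probabilities are pooled into a
#' single ROC/AUC.
#'
#' @param cohort Output of [delta_ct()] over a paired cohort.
#' @param markers Markers to consider (default: all in the cohort).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle (mandatory).
#' @param auc_cutoff Per-marker selection cutoff (default 0.7).
#' @param select Apply AUC selection before fitting (default TRUE).
#' @param ridge Ridge penalty passed to [fit_logistic()] (default 0).
#' @return Object of class `"lncsig_signature"`: list with `per_marker`
#'   (tibble from [marker_roc()] + `selected`), `selected`, `pooled_roc`
#'   (`"lncsig_roc"`), `pooled_auc`, `predictions` (tibble `patient`,
#'   `tissue`, `fold`, `probability`, `label`), `k`, `seed`.
#' @export
crossval_signature <- function(cohort, markers = NULL, k = 10, seed,
                               auc_cutoff = 0.7, select = TRUE, ridge = 0) {
  if (missing(seed)) abort("seed is mandatory")
  if (!is.null(markers)) cohort <- filter(cohort, .data$marker %in% markers)
  per_marker <- marker_roc(cohort)
  selected <- if (select) {
    select_signature(per_marker, cutoff = auc_cutoff, fallback_all = TRUE)
  } else per_marker$marker
  per_marker$selected <- per_marker$marker %in% selected &
    (!select | per_marker$auc > auc_cutoff)
  wide <- cohort %>%
    filter(.data$marker %in% selected, !.data$missing) %>%
    select("patient", "tissue", "marker", "delta_ct") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "delta_ct") %>%
    tidyr::drop_na()
  n <- nrow(wide)
  if (n < k) abort("k exceeds the number of samples")
  wide$label <- as.integer(wide$tissue == "tumour")
  wide$fold <- .make_folds(wide$patient, k, seed)
  X <- as.matrix(wide[, selected, drop = FALSE])
  prob <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- wide$fold == f
    fit <- fit_logistic(X[!test, , drop = FALSE], wide$label[!test],
                        ridge = ridge)
    prob[test] <- predict(fit, X[test, , drop = FALSE])
  }
  pooled <- roc_auc(prob, wide$label)
  structure(list(
    per_marker = per_marker, selected = selected,
    pooled_roc = pooled, pooled_auc = pooled$auc,
    predictions = tibble(patient = wide$patient, tissue = wide$tissue,
                         fold = wide$fold, probability = prob,
                         label = wide$label),
    k = k, seed = seed),
    class = "lncsig_signature")
}

#' @export
print.lncsig_signature <- function(x, ...) {
  cat(sprintf("Signature: %d marker(s) selected of %d; pooled %d-fold CV AUC = %.4f (seed %d)\n",
              length(x$selected), nrow(x$per_marker), x$k, x$pooled_auc,
              x$seed))
  invisible(x)
}

#' @method tidy lncsig_signature
#' @export
tidy.lncsig_signature <- function(x, ...) x$per_marker

#' @method glance lncsig_signature
#' @export
glance.lncsig_signature <- function(x, ...) {
  tibble(pooled_auc = x$pooled_auc, n_selected = length(x$selected),
         n_markers = nrow(x$per_marker), k = x$k, seed = x$seed,
         n_samples = nrow(x$predictions))
}

#' @method autoplot lncsig_signature
#' @export
autoplot.lncsig_signature <- function(object, ...) {
  autoplot(object$pooled_roc) +
    ggplot2::labs(title = sprintf("%d-fold CV pooled AUC = %.3f",
                                  object$k, object$pooled_auc))
}

#' Hierarchically cluster markers and patients on delta-Ct
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' marker-by-patient delta-Ct matrix, as used to display tumour expression
#' signatures. `hclust` resolves distance ties deterministically by element
#' index. Axes with fewer than 2 items get the trivial ordering.
#'
#' @param mat Numeric matrix, rows = markers, columns = patients; no missing
#'   cells.
#' @return List with `marker_order` and `patient_order` (integer leaf
#'   orderings) and the two `hclust` objects (`NULL` for trivial axes).
#' @export
cluster_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("delta-Ct matrix contains missing cells; impute or drop upstream")
  cl_axis <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    list(order = hc$order, hclust = hc)
  }
  rowcl <- cl_axis(mat)
  colcl <- cl_axis(t(mat))
  list(marker_order = rowcl$order, patient_order = colcl$order,
       marker_hclust = rowcl$hclust, patient_hclust = colcl$hclust)
}
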