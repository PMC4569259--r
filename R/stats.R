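#' Independent two-sample t test
#'
#' Pooled-variance two-sample t test (the primary variant); Welch's unequal-
#' variance form is available via \code{var_equal = FALSE}.  Missing values
#' are dropped per group.
#'
#' @param x,y Numeric vectors, each with >= 2 non-missing values.
#' @param var_equal Pool variances (default \code{TRUE}).
#' @return List: \code{t}, \code{p} (two-sided), \code{df}, \code{method}.
#' @examples
#' independent_t_test(c(1, 2, 3), c(4, 5, 6))$t  # -3.674
#' @export
independent_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 non-missing values")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       method = if (var_equal) "pooled" else "welch")
}

# Dunn-style pairwise rank z tests on the pooled ranks, with tie correction
.dunn_pairwise <- function(groups, p_adjust) {
  all_x <- unlist(groups, use.names = FALSE)
  n_tot <- length(all_x)
  rk <- rank(all_x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  mean_rank <- vapply(seq_along(groups), function(i)
    mean(rk[starts[i]:ends[i]]), numeric(1))
  ties <- table(all_x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  out <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    stringsAsFactors = FALSE)
  out$z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / sizes[i] + 1 / sizes[j]))
    (mean_rank[i] - mean_rank[j]) / se
  }, numeric(1))
  out$p <- stats::p.adjust(2 * stats::pnorm(-abs(out$z)), method = p_adjust)
  # two-group Kruskal-Wallis H per pair, for comparison with software that
  # reports pairwise H statistics
  out$h_pair <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    unname(stats::kruskal.test(list(groups[[i]], groups[[j]]))$statistic)
  }, numeric(1))
  out$p_pair <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    stats::kruskal.test(list(groups[[i]], groups[[j]]))$p.value
  }, numeric(1))
  out
}

#' Kruskal-Wallis test with pairwise rank comparisons
#'
#' Omnibus Kruskal-Wallis H (with tie correction) over all groups, followed by
#' Dunn-style pairwise z tests on the pooled ranks (tie-corrected, two-sided,
#' unadjusted by default).  Pairwise two-group Kruskal-Wallis H statistics are
#' also reported for each pair.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each non-empty
#'   after dropping missing values).
#' @param p_adjust Multiplicity adjustment for the Dunn p values (a
#'   [stats::p.adjust()] method; default \code{"none"}).
#' @return List: \code{h}, \code{p}, \code{df} (omnibus), \code{pairwise}
#'   (data.frame: group1, group2, z, p, h_pair, p_pair).
#' @export
kruskal_wallis_pairwise <- function(groups, p_adjust = "none") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  kw <- stats::kruskal.test(groups)
  list(h = unname(kw$statistic), p = kw$p.value,
       df = unname(kw$parameter),
       pairwise = .dunn_pairwise(groups, p_adjust))
}

#' Fit the three-ratio logistic grading model
#'
#' Unpenalized maximum-likelihood logistic regression of grade group
#' (HGG = 1, LGG = 0) on the metabolite ratios, by iteratively reweighted
#' least squares.  Coefficients are reported in the convention
#' \deqn{p = 1 / (1 + e^{-(-a + b\,Cho/Cr + c\,Cho/NAA + d\,LL/Cr)})}
#' i.e. \code{a} is minus the intercept.  Only complete cases on the chosen
#' predictors are used (rows with missing LL/Cr drop out only when LL/Cr is a
#' predictor, as with two-predictor fits to Siemens-derived ratios).
#'
#' @param records \code{case_records} data.frame (or any data.frame with the
#'   predictor columns and either \code{grade_group} or a 0/1 \code{outcome}
#'   column).
#' @param predictors Character vector, a subset of
#'   \code{c("cho_cr", "cho_naa", "ll_cr")} in combination-formula order (b, c, d).
#' @return An object of class \code{"ratio_logit"}: \code{coefficients} (named
#'   a, b, c, d as applicable), \code{fit} (the underlying \code{glm}),
#'   \code{converged}, \code{n}, \code{predictors}.
#' @export
fit_logistic_ratios <- function(records,
                             predictors = c("cho_cr", "cho_naa", "ll_cr")) {
  stopifnot(all(predictors %in% c("cho_cr", "cho_naa", "ll_cr")))
  df <- as.data.frame(records)
  y <- if (!is.null(df$outcome)) as.numeric(df$outcome)
       else if (!is.null(df$grade_group)) as.numeric(df$grade_group == "HGG")
       else stop("need a 'grade_group' or 0/1 'outcome' column")
  keep <- stats::complete.cases(df[predictors]) & !is.na(y)
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n == 0L) stop("no complete cases")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: both classes must be present")
  if (n < 10L) warning(sprintf("only %d complete cases; fit is fragile", n))
  form <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + ")))
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = cbind(df[predictors], y = y),
               family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  # a near-zero deviance means the binary outcome is fitted perfectly:
  # complete separation (glm's own boundary warning does not always fire)
  if (fit$deviance < 1e-6 ||
      (sep_flag && any(abs(cf[-1]) > 15, na.rm = TRUE)))
    stop("perfect (or quasi-perfect) separation: coefficients diverge")
  if (anyNA(cf))
    stop("degenerate fit: collinear or constant predictors")
  letters_bcd <- c(cho_cr = "b", cho_naa = "c", ll_cr = "d")
  coefs <- c(-unname(cf[1]), unname(cf[-1]))
  names(coefs) <- c("a", unname(letters_bcd[predictors]))
  structure(list(coefficients = coefs, fit = fit,
                 converged = fit$converged, n = n, predictors = predictors),
            class = "ratio_logit")
}

#' @export
coef.ratio_logit <- function(object, ...) object$coefficients

#' @export
print.ratio_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic ratio-combination model (n = %d, %s)\n  p = 1/(1 + exp(-(-a + %s)))\n",
    x$n, if (x$converged) "converged" else "NOT converged",
    paste(names(x$coefficients)[-1], x$predictors, sep = "*",
          collapse = " + ")))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Evaluate the logistic ratio-combination probability
#'
#' Computes \eqn{1 / (1 + e^{-(-a + b\,Cho/Cr + c\,Cho/NAA + d\,LL/Cr)})}.
#' Coefficients absent from the model (e.g. \code{d} in a two-predictor fit)
#' contribute nothing.
#'
#' @param model An \code{ratio_logit}, or a named numeric vector of
#'   coefficients (\code{a}, \code{b}, \code{c}, \code{d}).
#' @param cho_cr,cho_naa,ll_cr Ratio values (vectors recycle as usual).
#' @return Probability in (0, 1) for finite inputs.
#' @examples
#' predict_probability(c(a = 4.733, b = 1.580, c = 1.290, d = 0.698),
#'                     cho_cr = 1, cho_naa = 1, ll_cr = 1)  # 0.238
#' @export
predict_probability <- function(model, cho_cr, cho_naa, ll_cr = 0) {
  cf <- if (inherits(model, "ratio_logit")) model$coefficients else model
  g <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  eta <- -g("a") + g("b") * cho_cr + g("c") * cho_naa + g("d") * ll_cr
  1 / (1 + exp(-eta))
}

#' @export
predict.ratio_logit <- function(object, newdata, ...) {
  predict_probability(object,
                      cho_cr = newdata$cho_cr %||% 0,
                      cho_naa = newdata$cho_naa %||% 0,
                      ll_cr = newdata$ll_cr %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate grade outcomes from the logistic model
#'
#' Draws Bernoulli outcomes at the model's predicted probabilities for the
#' given ratio table, e.g. for parameter-recovery experiments.
#'
#' @param object An \code{ratio_logit}.
#' @param nsim Number of replicate outcome vectors.
#' @param seed Optional integer seed.
#' @param newdata data.frame of ratio columns (defaults to the fitting data).
#' @param ... Unused.
#' @return data.frame with \code{nsim} columns of 0/1 outcomes.
#' @export
simulate.ratio_logit <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$fit$data
  p <- predict(object, newdata)
  out <- as.data.frame(lapply(seq_len(nsim), function(i)
    stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Empirical ROC analysis with Youden cut-off
#'
#' Builds the empirical ROC over thresholds at midpoints between consecutive
#' distinct scores plus infinite sentinels (prediction rule: score >=
#' threshold is positive).  AUC is the trapezoidal area, which equals the
#' normalized Mann-Whitney U statistic with half credit for ties.  The best
#' cut-off maximizes Youden's J = sensitivity + specificity - 1; ties on J
#' are broken toward the lower threshold.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return An object of class \code{"roc_result"}: \code{curve} (data.frame:
#'   threshold, sensitivity, specificity in percent), \code{auc},
#'   \code{best_cutoff}, \code{sens_at_cutoff}, \code{spec_at_cutoff} (in
#'   percent), \code{youden_j}.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present in 'labels'")
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thresholds, function(th)
    100 * sum(scores >= th & labels == 1L) / n_pos, numeric(1))
  spec <- vapply(thresholds, function(th)
    100 * sum(scores < th & labels == 0L) / n_neg, numeric(1))
  # trapezoid over (FPR, TPR), thresholds descending in FPR
  fpr <- (100 - spec) / 100
  tpr <- sens / 100
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  j <- sens + spec - 100
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.min(thresholds[best])]
  structure(list(
    curve = data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = spec),
    auc = auc,
    best_cutoff = thresholds[best],
    sens_at_cutoff = sens[best],
    spec_at_cutoff = spec[best],
    youden_j = j[best] / 100),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; best cut-off %.3f (sensitivity %.1f%%, specificity %.1f%%)\n",
    x$auc, x$best_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot((100 - x$curve$specificity) / 100, x$curve$sensitivity / 100,
                 type = "s", xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Group summaries of metabolite ratios
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of each
#' ratio per group, with missing values excluded cell-wise and the per-cell n
#' reported.
#'
#' @param records \code{case_records} data.frame.
#' @param by Grouping column: \code{"grade_group"} or \code{"area"}.
#' @return data.frame: \code{group}, \code{ratio}, \code{n}, \code{mean},
#'   \code{sd} (sd is \code{NA} for a single observation; empty groups yield
#'   empty cells with n = 0).
#' @export
summarize_cohort <- function(records, by = c("grade_group", "area")) {
  by <- match.arg(by)
  df <- as.data.frame(records)
  groups <- unique(df[[by]])
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- df[df[[by]] == g, , drop = FALSE]
    do.call(rbind, lapply(.ratio_cols, function(rc) {
      v <- sub[[rc]]
      v <- v[!is.na(v)]
      data.frame(group = g, ratio = rc, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
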