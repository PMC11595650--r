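#' Normality-gated two-group comparison
#'
#' For continuous samples, normality of each group is assessed with a
#' Shapiro-Wilk test at level 0.05; if both pass, a Welch two-sample t-test
#' is used, otherwise the Mann-Whitney U test (a mixed pair takes the
#' nonparametric path, the conservative choice). For categorical data the
#' samples are taken as the two rows of a contingency table: Fisher's exact
#' test for 2x2, chi-squared otherwise.
#'
#' @param x,y Continuous: numeric samples (n >= 3 each). Categorical: counts
#'   per category, same length.
#' @param continuous Whether `x` and `y` are measurements (default) or
#'   category counts.
#' @param shapiro_alpha Gate level for the normality test.
#' @return List of class `group_test`: `test` (name used), `statistic`,
#'   `p`, and per-group summaries.
#' @export
#' @examples
#' compare_groups(rnorm(30), rnorm(30, 1))
#' compare_groups(c(10, 0), c(0, 10), continuous = FALSE)  # Fisher
compare_groups <- function(x, y, continuous = TRUE, shapiro_alpha = 0.05) {
  if (continuous) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L)
      stop("each continuous sample needs n >= 3")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(structure(list(test = "degenerate (zero variance)",
                            statistic = NA_real_, p = 1,
                            summary = .gsum(x, y),
                            zero_variance = TRUE),
                       class = "group_test"))
    }
    # shapiro.test needs some spread; a constant sample is non-Gaussian
    norm_ok <- function(v) {
      if (length(v) > 5000) v <- sample(v, 5000)
      stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > shapiro_alpha
    }
    if (norm_ok(x) && norm_ok(y)) {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      test <- "Welch t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      test <- "Mann-Whitney U"
    }
    structure(list(test = test, statistic = unname(ht$statistic),
                   p = ht$p.value, summary = .gsum(x, y),
                   zero_variance = FALSE),
              class = "group_test")
  } else {
    if (length(x) != length(y)) stop("count vectors must align")
    tab <- rbind(x, y)
    if (any(tab < 0) || sum(tab) == 0) stop("invalid counts")
    if (ncol(tab) == 2L) {
      ht <- stats::fisher.test(tab)
      test <- "Fisher exact"
      stat <- NA_real_
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab))
      test <- "chi-squared"
      stat <- unname(ht$statistic)
    }
    structure(list(test = test, statistic = stat, p = ht$p.value,
                   summary = list(counts = tab)),
              class = "group_test")
  }
}

.gsum <- function(x, y) {
  list(a = c(n = length(x), mean = mean(x), sd = stats::sd(x)),
       b = c(n = length(y), mean = mean(y), sd = stats::sd(y)))
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$test, ": p =", format.pval(x$p), "\n")
  invisible(x)
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) reporting
#' per-covariate odds ratios with Wald 95 percent confidence intervals.
#' Complete or quasi-complete separation is flagged as non-converged.
#'
#' @param outcome Binary vector (0/1 or logical) with both classes present.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column; one is added).
#' @return List of class `logistic_fit`: `table` (one row per covariate:
#'   estimate, or, ci_low, ci_high, p), `converged`, `n`, and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(outcome, covariates) {
  y <- as.integer(outcome)
  if (anyNA(y) || !all(y %in% 0:1)) stop("outcome must be binary")
  if (length(unique(y)) < 2L)
    stop("outcome must contain both classes")
  X <- as.data.frame(covariates)
  if (nrow(X) != length(y)) stop("covariates and outcome lengths differ")
  for (nm in names(X)) {
    v <- X[[nm]]
    if (is.numeric(v) && stats::sd(v) == 0)
      stop("constant covariate: ", nm)
  }
  dat <- cbind(data.frame(.y = y), X)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- summary(fit)$coefficients
  est <- coefs[, "Estimate"]
  se <- coefs[, "Std. Error"]
  separated <- warned || any(abs(est[-1]) > 15) || any(se > 100)
  tab <- data.frame(term = rownames(coefs),
                    estimate = est,
                    or = exp(est),
                    ci_low = exp(est - stats::qnorm(0.975) * se),
                    ci_high = exp(est + stats::qnorm(0.975) * se),
                    p = coefs[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab,
                 converged = fit$converged && !separated,
                 separation = separated,
                 n = length(y), glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) cat("[non-converged / separation]\n")
  df <- x$table
  df$or <- round(df$or, 3); df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  print(df[, c("term", "or", "ci_low", "ci_high", "p")], row.names = FALSE)
  invisible(x)
}

#' Linear risk score from a fitted logistic model
#'
#' Evaluates the linear predictor (log-odds) for new subjects; the score is
#' the input to [roc_auc()] for covariate-adjusted discrimination analyses.
#'
#' @param covariates Data frame with the same covariate columns used in the
#'   fit.
#' @param fit A `logistic_fit` from [fit_logistic()].
#' @return Numeric log-odds per subject.
#' @export
composite_score <- function(covariates, fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- as.data.frame(covariates)
  need <- setdiff(names(fit$glm$model), ".y")
  if (!all(need %in% names(X)))
    stop("covariate mismatch: need ", paste(need, collapse = ", "))
  as.numeric(stats::predict(fit$glm, newdata = X, type = "link"))
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' The AUC is computed from ranks (the Mann-Whitney concordance statistic
#' with midrank tie correction): the probability that a randomly chosen
#' positive scores above a randomly chosen negative, counting ties as one
#' half. The confidence interval is a seeded percentile bootstrap over
#' subjects, stratified by class so every resample retains both classes.
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels Binary class labels (0/1 or logical).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Seed for the bootstrap; fixed seed gives an identical CI.
#' @param conf Confidence level.
#' @return List of class `roc_result`: `auc`, `ci` (length 2), `n_pos`,
#'   `n_neg`, `n_boot`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1), n_boot = 200, seed = 1)$auc  # 0.75
roc_auc <- function(scores, labels, n_boot = 2000, seed = NULL,
                    conf = 0.95) {
  lab <- as.logical(as.integer(labels))
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  auc_of <- function(s, l) {
    r <- rank(s)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  auc <- auc_of(scores, lab)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ip <- which(lab); iq <- which(!lab)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(ip, n_pos, replace = TRUE),
               sample(iq, n_neg, replace = TRUE))
      auc_of(scores[idx], lab[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(auc = auc, ci = ci, n_pos = n_pos, n_neg = n_neg,
                 n_boot = n_boot),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%%CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}
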