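# Posterior-draw decision machinery: REML point fits (lm / lme4), 10000
# flat-prior joint-posterior draws of the coefficients (sigma^2 from its
# scaled inverse-chi-squared posterior under p(sigma^2) ~ 1/sigma^2,
# beta multivariate normal), 95% credible intervals, and the "posterior
# probability of difference > 95%" decision rule.

#' Fit a (mixed) linear model for posterior simulation
#'
#' Point estimation is standard numerics: ordinary least squares when
#' `random` is `NULL`, otherwise REML via [lme4::lmer()]. Random-effect
#' structures that fail on small data degrade gracefully: terms are
#' dropped one by one (with a notice) until the fit succeeds, falling
#' back to `lm`.
#'
#' @param data model data.frame.
#' @param fixed fixed-effects formula, e.g. `ars ~ treatment * call_type`.
#' @param random `NULL` or a one-sided formula of random terms, e.g.
#'   `~ (1 | bird_id) + (1 | day_index)`.
#' @return Object of class `model_fit`: coefficient names, estimates
#'   `beta`, covariance `vcov`, residual `sigma`, residual `df`,
#'   `random_used` (the structure actually fitted), residual diagnostics
#'   (`shapiro_p` when computable, `scale_location_cor`), and the design
#'   metadata needed to build contrast rows.
#' @export
fit_model <- function(data, fixed, random = NULL) {
  data <- as.data.frame(data)
  rand_terms <- if (is.null(random)) character(0) else {
    attr(stats::terms(random), "term.labels")
  }
  fit <- NULL
  used <- rand_terms
  repeat {
    if (length(used) == 0L) {
      fit <- stats::lm(fixed, data = data)
      break
    }
    f <- stats::as.formula(paste(deparse(fixed, width.cutoff = 500L),
                                 paste0("(", used, ")", collapse = " + "),
                                 sep = " + "))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(f, data = data, REML = TRUE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
    message("random term (", used[length(used)],
            ") dropped: fit failed on these data")
    used <- used[-length(used)]
  }
  is_mixed <- inherits(fit, "merMod")
  beta <- if (is_mixed) lme4::fixef(fit) else stats::coef(fit)
  if (any(is.na(beta))) {
    stop("rank-deficient fixed-effects design; aliased term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  shapiro_p <- if (length(res) >= 3L && length(res) <= 5000L) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  sl_cor <- if (length(res) >= 3L && stats::sd(fitted) > 0 &&
                stats::sd(abs(res)) > 0) {
    stats::cor(abs(res), fitted)
  } else NA_real_
  ff <- stats::formula(fixed)
  mf <- stats::model.frame(lme4::nobars(ff), data = data)
  xlev <- lapply(Filter(function(v) is.factor(v) || is.character(v), mf),
                 function(v) levels(as.factor(v)))
  structure(list(
    beta = beta, vcov = V,
    sigma = stats::sigma(fit), df = length(res) - length(beta),
    n_obs = length(res), type = if (is_mixed) "lmer" else "lm",
    random_requested = rand_terms, random_used = used,
    fixed = ff, xlevels = xlev,
    diagnostics = list(shapiro_p = shapiro_p, scale_location_cor = sl_cor)
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: %d coefficient(s), sigma = %.4g, n = %d\n",
              x$type, length(x$beta), x$sigma, x$n_obs))
  if (length(x$random_used) > 0L) {
    cat("  random terms:", paste(x$random_used, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw from the flat-prior joint posterior of the coefficients
#'
#' For an OLS fit, the flat-prior posterior is the standard conjugate
#' form: `sigma^2 | y` is scaled inverse-chi-squared
#' (`sigma_hat^2 * df / chisq(df)`) and `beta | sigma^2, y` is
#' multivariate normal centred at `beta_hat` with the fit's covariance
#' rescaled by `sigma^2 / sigma_hat^2`. For mixed fits the variance
#' components beyond the residual are fixed at their REML estimates
#' (stated approximation) and `beta` is drawn from
#' `MVN(beta_hat, vcov)`.
#'
#' @param fit a [fit_model()] result.
#' @param n number of draws (default 10000).
#' @param seed optional integer seed; fixed seed reproduces the matrix.
#' @return `n x p` matrix of coefficient draws (named columns) with the
#'   sigma draws in attribute `"sigma"`.
#' @export
posterior_draws <- function(fit, n = 10000, seed = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(fit$beta)
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
    stop("coefficient covariance is not positive semi-definite",
         call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  sigma_draws <- if (fit$type == "lm" && fit$df > 0) {
    fit$sigma * sqrt(fit$df / stats::rchisq(n, fit$df))
  } else rep(fit$sigma, n)
  Z <- matrix(stats::rnorm(n * p), n, p)
  scale <- if (fit$type == "lm" && fit$sigma > 0) {
    sigma_draws / fit$sigma
  } else rep(1, n)
  draws <- sweep(Z %*% t(L), 1L, scale, "*") +
    matrix(fit$beta, n, p, byrow = TRUE)
  colnames(draws) <- names(fit$beta)
  attr(draws, "sigma") <- sigma_draws
  draws
}

#' Summarize a contrast of posterior draws
#'
#' Computes the posterior mean, the 95% credible interval (2.5-97.5%
#' percentiles of the draws), and the directional posterior probability
#' `prob_direction` = the larger of the fractions of draws above/below
#' zero. An effect is `meaningful` when `prob_direction > 0.95`.
#'
#' @param draws draw matrix from [posterior_draws()].
#' @param contrast numeric vector of length `ncol(draws)`.
#' @param name label for the contrast.
#' @return One-row data.frame: `contrast`, `mean`, `cri_low`, `cri_high`,
#'   `prob_positive`, `prob_negative`, `prob_direction`, `direction`,
#'   `decision`.
#' @export
summarize_contrast <- function(draws, contrast, name = "contrast") {
  stopifnot(length(contrast) == ncol(draws))
  vals <- as.numeric(draws %*% contrast)
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  p_pos <- mean(vals > 0)
  p_neg <- mean(vals < 0)
  prob_dir <- max(p_pos, p_neg)
  data.frame(
    contrast = name, mean = mean(vals), cri_low = q[1L], cri_high = q[2L],
    prob_positive = p_pos, prob_negative = p_neg,
    prob_direction = prob_dir,
    direction = if (p_pos >= p_neg) "positive" else "negative",
    decision = if (prob_dir > 0.95) "meaningful" else "not-meaningful",
    stringsAsFactors = FALSE)
}

# fixed-effects design row(s) for new data, using the fit's factor levels
model_design_rows <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(lme4::nobars(fit$fixed)))
  stats::model.matrix(tt, data = newdata, xlev = fit$xlevels)
}

#' Run the standard treatment contrasts of an experiment table
#'
#' Fits `response ~ treatment * type` (REML, with optional random terms),
#' draws from the flat-prior posterior, and summarizes the breeding-onset
#' contrast (B minus NB) within every level of `type` that occurs under
#' both treatments. Missing cells are skipped with a notice; an empty
#' dataset returns an empty report. No multiple-testing correction is
#' applied; the report carries the number of contrasts so users can
#' judge.
#'
#' @param records data.frame of per-observation responses (e.g. ARS
#'   records or playback scores).
#' @param response name of the response column (default `"ars"`).
#' @param type_col column defining the within-level contrasts (default
#'   `"call_type"`; use `"stimulus_label"` for playback tables).
#' @param treatment_col treatment column with levels NB/B (default
#'   `"treatment"`).
#' @param random optional one-sided random-effects formula passed to
#'   [fit_model()], e.g. `~ (1 | bird_id) + (1 | day_index)`.
#' @param n_draws posterior draws (default 10000).
#' @param seed optional seed for the draws.
#' @return Data frame with one [summarize_contrast()] row per type level,
#'   plus columns `type` and `n_obs`; attribute `"fit"` holds the
#'   [fit_model()] object.
#' @export
run_paper_contrasts <- function(records, response = "ars",
                                type_col = "call_type",
                                treatment_col = "treatment",
                                random = NULL, n_draws = 10000,
                                seed = NULL) {
  empty <- data.frame(
    contrast = character(), mean = numeric(), cri_low = numeric(),
    cri_high = numeric(), prob_positive = numeric(),
    prob_negative = numeric(), prob_direction = numeric(),
    direction = character(), decision = character(), type = character(),
    n_obs = integer(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  df <- data.frame(
    y = records[[response]],
    treatment = factor(records[[treatment_col]], levels = TREATMENTS),
    type = factor(records[[type_col]]))
  extra <- setdiff(names(records), c(response, type_col, treatment_col))
  for (cn in extra) df[[cn]] <- records[[cn]]
  df <- df[stats::complete.cases(df[, c("y", "treatment", "type")]), ,
           drop = FALSE]
  if (nrow(df) == 0L || length(unique(df$treatment)) < 2L) {
    message("no complete NB/B design: empty contrast report")
    return(empty)
  }
  # a type level observed under only one treatment cannot support the
  # B-NB contrast and would alias the interaction design: drop it
  cells <- table(df$type, df$treatment)
  complete <- rownames(cells)[apply(cells > 0L, 1L, all)]
  for (lv in setdiff(rownames(cells), complete)) {
    message("contrast skipped for '", lv, "': missing treatment cell")
  }
  df <- droplevels(df[df$type %in% complete, , drop = FALSE])
  if (nrow(df) == 0L || length(unique(df$treatment)) < 2L) {
    message("no complete NB/B design: empty contrast report")
    return(empty)
  }
  form <- if (nlevels(df$type) >= 2L) y ~ treatment * type else y ~ treatment
  fit <- fit_model(df, form, random = random)
  draws <- posterior_draws(fit, n = n_draws, seed = seed)
  out <- list()
  for (lv in levels(df$type)) {
    cells <- table(df$treatment[df$type == lv])
    if (any(cells == 0L)) {
      message("contrast skipped for '", lv, "': missing treatment cell")
      next
    }
    nd_b <- data.frame(treatment = factor("B", levels = TREATMENTS),
                       type = factor(lv, levels = levels(df$type)))
    nd_nb <- data.frame(treatment = factor("NB", levels = TREATMENTS),
                        type = factor(lv, levels = levels(df$type)))
    cvec <- as.numeric(model_design_rows(fit, nd_b) -
                         model_design_rows(fit, nd_nb))
    row <- summarize_contrast(draws, cvec,
                              name = paste0("B-NB @ ", lv))
    row$type <- lv
    row$n_obs <- sum(cells)
    out[[lv]] <- row
  }
  report <- rbind_df(c(out))
  if (is.null(report)) report <- empty
  attr(report, "fit") <- fit
  attr(report, "n_contrasts") <- nrow(report)
  report
}

#' Write a contrast report to disk
#'
#' Serializes a [run_paper_contrasts()] report as CSV plus a short
#' human-readable text summary.
#'
#' @param report data.frame from [run_paper_contrasts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_contrast_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  fit <- attr(report, "fit")
  lines <- c(
    sprintf("Contrast report: %d contrast(s), no multiplicity correction",
            nrow(report)),
    if (!is.null(fit)) sprintf(
      "Model: %s; random terms used: %s", fit$type,
      if (length(fit$random_used) > 0L)
        paste(fit$random_used, collapse = ", ") else "none"),
    "")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "%-28s mean %8.4f  95%% CrI [%8.4f, %8.4f]  P(%s) = %.4f  -> %s",
      r$contrast, r$mean, r$cri_low, r$cri_high, r$direction,
      r$prob_direction, r$decision))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
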