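#' Fit the state-similarity mixed-effects model
#'
#' Fits `rating ~ code + (code | participant) + (code | pair)` by REML,
#' where `code` encodes the target contrast: self vs. other (0/1), close
#' vs. far (0/1), a continuous social-distance predictor, or a dummy-coded
#' target factor (for LS-means post-hocs). The maximal random structure is
#' relaxed on singular fits along a fallback ladder (drop slope-intercept
#' correlations, drop pair slopes, drop participant slopes, intercepts
#' only); the structure actually used is recorded. Fixed-effect p values
#' use the Satterthwaite degrees-of-freedom approximation.
#'
#' @param data rating table: columns `participant`, `target`, `state_i`,
#'   `state_j`, `rating` (a `pair` column is built if absent). The
#'   `"distance"` contrast additionally needs a `distance` column (one
#'   value per participant x target), which is z-scored across
#'   participant x target cells before entry.
#' @param fixed `"self_other"`, `"close_far"`, `"distance"`, or
#'   `"target_factor"`.
#' @param reference target treated as the baseline level; defaults to the
#'   first target in `data` order ("self" when present).
#' @param df_method `"satterthwaite"` (the reference behavior) or
#'   `"residual"`, which skips the Satterthwaite computation and reports
#'   residual-degrees-of-freedom p values; the choice is recorded in the
#'   result. With hundreds of grouping levels the two are nearly
#'   indistinguishable, so `"residual"` is the pragmatic option inside
#'   large simulation loops.
#' @param start optional variance-parameter (theta) starting values, e.g.
#'   `lme4::getME(previous_fit, "theta")`, to warm-start replicate fits.
#' @return Object of class `lmm_result`: list with `fixed` (data frame of
#'   b, beta, SE, t, df, p per fixed effect), `r2` (marginal,
#'   conditional), `varcor`, `sigma`, `random_structure`, `singular`,
#'   `df_method`, `model`, `contrast`.
#' @export
fit_state_similarity_lmm <- function(data,
                                     fixed = c("self_other", "close_far",
                                               "distance", "target_factor"),
                                     reference = NULL,
                                     df_method = c("satterthwaite",
                                                   "residual"),
                                     start = NULL) {
  fixed <- match.arg(fixed)
  df_method <- match.arg(df_method)
  need <- c("participant", "target", "rating")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants")
  if (is.null(data[["pair"]])) {
    if (is.null(data[["state_i"]]) || is.null(data[["state_j"]]))
      stop("data needs a pair column or state_i/state_j")
    data$pair <- paste(pmin(data[["state_i"]], data[["state_j"]]),
                       pmax(data[["state_i"]], data[["state_j"]]), sep = "-")
  }
  if (length(unique(data[["pair"]])) < 2) stop("need at least 2 state pairs")

  tg <- unique(data$target)
  reference <- reference %||% (if ("self" %in% tg) "self" else tg[1])
  if (fixed == "target_factor") {
    if (length(tg) < 3) stop("target_factor contrast needs >= 3 levels")
    data$code <- factor(data$target,
                        levels = c(reference, setdiff(tg, reference)))
    term <- "code"
  } else if (fixed == "distance") {
    if (is.null(data[["distance"]]))
      stop("'distance' contrast needs a distance column")
    data$code <- as.numeric(scale(data[["distance"]]))
    term <- "code"
  } else {
    if (length(tg) < 2)
      stop("target contrast is constant: only one target present")
    data$code <- as.numeric(data$target != reference)
    if (var(data$code) == 0)
      stop("target contrast is constant: only one target present")
    term <- "code"
  }

  ladder <- c("rating ~ code + (1 + code | participant) + (1 + code | pair)",
              "rating ~ code + (1 + code || participant) + (1 + code || pair)",
              "rating ~ code + (1 + code || participant) + (1 | pair)",
              "rating ~ code + (1 | participant) + (1 | pair)")
  fit <- NULL
  used <- NA_character_
  engine <- if (df_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  for (fml in ladder) {
    # do.call inlines evaluated arguments into the call, so lmerTest's
    # internal re-evaluation of it is scope-independent
    args <- list(formula = stats::as.formula(fml), data = data,
                 REML = TRUE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
    if (fml == ladder[1] && !is.null(start)) args$start <- start
    cand <- tryCatch(
      suppressMessages(suppressWarnings(do.call(engine, args))),
      error = function(e) NULL)
    if (is.null(cand)) next
    fit <- cand
    used <- fml
    if (!lme4::isSingular(cand, tol = 1e-4)) break
  }
  if (is.null(fit))
    stop("mixed model failed to converge on every random structure")

  sm <- summary(fit)$coefficients
  rows <- grep("^code", rownames(sm))
  if (df_method == "residual") {
    rdf <- nrow(data) - ncol(lme4::getME(fit, "X"))
    sm <- cbind(sm, df = rdf,
                `Pr(>|t|)` = 2 * pt(abs(sm[, "t value"]), rdf,
                                    lower.tail = FALSE))
  }
  sd_y <- sd(data$rating)
  sd_x <- if (is.factor(data$code)) NA_real_ else sd(data$code)
  fixed_df <- data.frame(
    term = rownames(sm)[rows],
    b = sm[rows, "Estimate"],
    beta = if (is.factor(data$code)) NA_real_
           else sm[rows, "Estimate"] * sd_x / sd_y,
    se = sm[rows, "Std. Error"],
    t = sm[rows, "t value"],
    df = sm[rows, "df"],
    p = sm[rows, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  r2 <- r2_nakagawa(fit)
  structure(list(fixed = fixed_df, r2 = r2,
                 varcor = lme4::VarCorr(fit), sigma = stats::sigma(fit),
                 random_structure = used,
                 singular = lme4::isSingular(fit, tol = 1e-4),
                 df_method = df_method,
                 model = fit, contrast = fixed, reference = reference),
            class = "lmm_result")
}

#' @exportS3Method print lmm_result
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> contrast '%s' (reference: %s)\n", x$contrast,
              x$reference))
  print(transform(x$fixed, p = signif(p, 3)), digits = 3)
  cat(sprintf("marginal R2 = %.4f, conditional R2 = %.3f; random structure: %s%s\n",
              x$r2[["marginal"]], x$r2[["conditional"]],
              x$random_structure, if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Least-squares means post-hoc contrasts between targets
#'
#' Estimated marginal mean per target and all pairwise differences, with
#' Satterthwaite degrees of freedom, computed with \pkg{emmeans} on a
#' dummy-coded target fit.
#'
#' @param result an [fit_state_similarity_lmm()] result with
#'   `fixed = "target_factor"`, or such a fitted model.
#' @return List with `emmeans` and `contrasts` data frames.
#' @export
lsmeans_posthoc <- function(result) {
  model <- if (inherits(result, "lmm_result")) {
    if (result$contrast != "target_factor")
      stop("lsmeans_posthoc needs a fixed = 'target_factor' fit")
    result$model
  } else result
  em <- emmeans::emmeans(model, "code", lmer.df = "satterthwaite")
  ct <- emmeans::contrast(em, method = "pairwise", adjust = "none")
  list(emmeans = as.data.frame(em), contrasts = as.data.frame(ct))
}

#' Social-distance composite score
#'
#' Averages each participant x target's similarity, familiarity and
#' closeness ratings of the target (larger = socially closer) and reports
#' the mean pairwise Pearson correlation among the three component scores.
#'
#' @param scores data frame with columns `participant`, `target`,
#'   `similarity`, `familiarity`, `closeness`.
#' @param as_distance negate the composite so that larger = more distant?
#' @return `scores` with a `composite` column added; the mean
#'   inter-correlation is attached as attribute `mean_r`.
#' @export
social_distance_composite <- function(scores, as_distance = FALSE) {
  need <- c("similarity", "familiarity", "closeness")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop("missing component score(s): ", paste(miss, collapse = ", "))
  comp <- rowMeans(scores[, need])
  cm <- cor(scores[, need])
  mean_r <- mean(cm[lower.tri(cm)])
  scores$composite <- if (as_distance) -comp else comp
  attr(scores, "mean_r") <- mean_r
  scores
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Nakagawa's variance-partition R-squared with Johnson's extension to
#' random slopes: the random-effect variance of each grouping term is the
#' mean over observations of `x' Sigma x`, where `x` is the term's
#' design row and `Sigma` its estimated covariance. Marginal R2 is the
#' fixed-effect share of the total (fixed + random + residual) variance;
#' conditional R2 adds the random share to the numerator.
#'
#' @param fit a fitted `lmerMod` (or an [fit_state_similarity_lmm()]
#'   result).
#' @return Named numeric: `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "lmm_result")) fit <- fit$model
  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  var_f <- var(as.vector(X %*% beta))
  vc <- lme4::VarCorr(fit)
  var_r <- 0
  for (g in seq_along(vc)) {
    Sg <- as.matrix(vc[[g]])
    nm <- rownames(Sg)
    if (!all(nm %in% colnames(X)))
      stop("random-effect terms not in the fixed design: ",
           paste(setdiff(nm, colnames(X)), collapse = ", "))
    Xg <- X[, nm, drop = FALSE]
    var_r <- var_r + mean(rowSums((Xg %*% Sg) * Xg))
  }
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
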