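#' Fit the Menzerath mixed model of log call duration
#'
#' Fits, by restricted maximum likelihood (default), the linear mixed model
#'
#' \deqn{\log(d_{ijk}) = \beta_0 + \beta_1 \log(n_j) + \beta_2 \, pos_{ijk}
#'   + u_j + v_k + w_{pos} + \epsilon_{ijk}}
#'
#' where \eqn{d_{ijk}} is the duration of the call at position \eqn{pos} of
#' sequence \eqn{j} produced by individual \eqn{k}, and \eqn{n_j} is the
#' sequence size. Random intercepts are crossed: \eqn{u_j} per sequence,
#' \eqn{v_k} per individual, and \eqn{w} per ordinal-position category (the
#' position enters both as a numeric fixed effect and as a categorical random
#' intercept). Natural logarithms are used for both the response and the
#' sequence size. Menzerath's law corresponds to \eqn{\beta_1 < 0}.
#'
#' Degrees of freedom for the t statistics, p-values, and confidence
#' intervals use the Satterthwaite approximation by default
#' (`df_method = "satterthwaite"`), which matters here: the position slope's
#' sampling uncertainty is dominated by the position-category random
#' intercept, whose few levels leave only a handful of effective degrees of
#' freedom, and residual-df intervals undercover badly in that regime.
#' `df_method = "residual"` (`n_obs` minus the number of fixed effects) is
#' available for comparability with tools that apply no correction; the
#' method used is recorded in the result. With a single individual the
#' individual random intercept is inestimable and is dropped with a warning,
#' and likewise for a single position category.
#'
#' @param table A [call_table()].
#' @param include_singles Keep sequences of size one? When `FALSE` they are
#'   removed before fitting. Singletons contribute `log(1) = 0` to the size
#'   term and position 1; there is no other special casing.
#' @param reml Use REML (default) or ML.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @return An object of class `menzerath_fit`; see [coef.menzerath_fit()],
#'   [summary.menzerath_fit()].
#' @examples
#' tab <- simulate_call_table(preset_config("trained_crow",
#'   sequences_per_individual = 100L), seed = 42)
#' fit <- fit_menzerath(tab)
#' coef(fit)
#' @export
fit_menzerath <- function(table, include_singles = TRUE, reml = TRUE,
                          df_method = c("satterthwaite", "residual")) {
  stopifnot(inherits(table, "call_table"))
  df_method <- match.arg(df_method)
  if (!include_singles) {
    table <- filter_calls(table, exclude_singles = TRUE)
  }
  mf <- model_frame_calls(table)
  if (length(unique(mf$log_size)) < 2L) {
    stop_menzerath("model_error",
      "need at least 2 distinct sequence sizes to estimate the size slope")
  }
  fit_lmm_core(mf, fixed = "log_size + position", reml = reml,
               table = table, df_method = df_method)
}

# SEs from the fixed-effect covariance; NA when the covariance is
# degenerate (e.g. zero residual variance on a constant response)
safe_fixef_se <- function(model, k) {
  out <- tryCatch({
    v <- suppressWarnings(stats::vcov(model))
    sqrt(pmax(diag(as.matrix(v)), 0))
  }, error = function(e) rep(NA_real_, k))
  if (length(out) != k || !is.numeric(out)) rep(NA_real_, k) else out
}

# Satterthwaite df per fixed effect; NA where the approximation fails
satterthwaite_df <- function(model) {
  tryCatch(suppressMessages(suppressWarnings({
    mt <- lmerTest::as_lmerModLmerTest(model)
    sm <- summary(mt)$coefficients
    sm[, "df"]
  })), error = function(e) NULL)
}

# shared fitting path for the plain model and the group-interaction model
fit_lmm_core <- function(mf, fixed, reml, table,
                         df_method = "satterthwaite") {
  re_terms <- c("(1 | sequence_id)")
  if (nlevels(mf$individual_id) > 1L) {
    re_terms <- c(re_terms, "(1 | individual_id)")
  } else {
    warning("single individual: individual random intercept dropped (variance inestimable)")
  }
  if (nlevels(mf$position_cat) > 1L) {
    re_terms <- c(re_terms, "(1 | position_cat)")
  } else {
    warning("single position category: position random intercept dropped")
  }
  form <- stats::as.formula(paste("log_dur ~", fixed, "+",
                                  paste(re_terms, collapse = " + ")))
  msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(form, data = mf, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv_ok <- length(model@optinfo$conv$lme4) == 0L
  fe <- lme4::fixef(model)
  se <- safe_fixef_se(model, length(fe))
  df <- rep(nrow(mf) - length(fe), length(fe))
  if (identical(df_method, "satterthwaite")) {
    sdf <- satterthwaite_df(model)
    if (!is.null(sdf) && length(sdf) == length(fe) && all(is.finite(sdf))) {
      df <- as.numeric(sdf)
    } else {
      df_method <- "residual"   # fallback, recorded as such
    }
  }
  tval <- fe / se
  coefs <- data.frame(
    term = names(fe),
    estimate = as.numeric(fe),
    se = as.numeric(se),
    t = as.numeric(tval),
    df = df,
    p = 2 * stats::pt(-abs(as.numeric(tval)), df = df),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- data.frame(group = vc$grp, sd = vc$sdcor, variance = vc$vcov,
                        stringsAsFactors = FALSE)
  out <- list(
    coefficients = coefs,
    varcomp = varcomp,
    n_obs = nrow(mf),
    n_sequences = nlevels(mf$sequence_id),
    n_individuals = nlevels(mf$individual_id),
    formula = form,
    reml = reml,
    df_method = df_method,
    converged = conv_ok,
    singular = lme4::isSingular(model),
    messages = msgs,
    model = model,
    frame = mf
  )
  class(out) <- "menzerath_fit"
  out
}

#' Fit the pooled model with group interactions
#'
#' Pools two call tables under a group factor (e.g. training context, or
#' species) and fits the Menzerath model with a group main effect and
#' group-by-slope interactions:
#' `log(dur) ~ group * log(size) + group * position` plus the crossed random
#' intercepts. The interaction coefficients measure how the size and position
#' slopes differ between the two datasets. Sequence and individual ids are
#' namespaced by group internally, so the random-effect grouping never leaks
#' across datasets.
#'
#' @param table_a,table_b Two [call_table()]s. Their group labels (taken from
#'   `labels` or, by default, each table's context) must be distinct;
#'   `table_a`'s label is the reference level.
#' @param group_name Name of the group factor in the output (e.g.
#'   `"context"`, `"species"`).
#' @param labels Optional length-2 character vector of group labels.
#' @param include_singles,reml,df_method As in [fit_menzerath()].
#' @return A `menzerath_fit` whose `interactions` element holds the two
#'   interaction rows of the coefficient table.
#' @export
fit_group_interaction <- function(table_a, table_b, group_name = "group",
                                  labels = NULL, include_singles = TRUE,
                                  reml = TRUE,
                                  df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(table_a, "call_table"), inherits(table_b, "call_table"))
  if (is.null(labels)) {
    labels <- c(unique(table_a$context)[1], unique(table_b$context)[1])
  }
  if (labels[1] == labels[2]) {
    stop_menzerath("model_error",
      "group labels are identical; the two tables must carry distinct labels")
  }
  if (!include_singles) {
    table_a <- filter_calls(table_a, exclude_singles = TRUE)
    table_b <- filter_calls(table_b, exclude_singles = TRUE)
  }
  mfa <- model_frame_calls(table_a)
  mfb <- model_frame_calls(table_b)
  mfa$group <- labels[1]
  mfb$group <- labels[2]
  relabel <- function(mf, lab) {
    mf$sequence_id <- factor(paste(lab, as.character(mf$sequence_id),
                                   sep = ":"))
    mf$individual_id <- factor(paste(lab, as.character(mf$individual_id),
                                     sep = ":"))
    mf
  }
  mf <- rbind(relabel(mfa, labels[1]), relabel(mfb, labels[2]))
  mf$group <- factor(mf$group, levels = labels)
  mf$sequence_id <- factor(mf$sequence_id)
  mf$individual_id <- factor(mf$individual_id)
  mf$position_cat <- factor(mf$position_cat)
  out <- fit_lmm_core(mf, fixed = "group * log_size + group * position",
                      reml = reml, table = NULL, df_method = df_method)
  out$group_name <- group_name
  out$group_labels <- labels
  ix <- grepl(":", out$coefficients$term, fixed = TRUE)
  out$interactions <- out$coefficients[ix, , drop = FALSE]
  out
}

#' Fit the cued-number accuracy model
#'
#' Accuracy (proportion of correct trials) is computed per participant and
#' cue number and regressed on cue number with per-participant random
#' intercepts and random slopes:
#' `accuracy ~ cue_number + (cue_number | participant_id)`.
#' The model is linear on the proportion-correct scale (0-1), so the cue
#' coefficient is the change in success probability per cue increment.
#'
#' @param trials A data frame with columns `participant_id`, `cue_number`,
#'   `correct` (logical or 0/1), as produced by [simulate_trials()].
#' @param reml Use REML (default) or ML.
#' @return A `menzerath_fit` whose coefficient table contains the
#'   `cue_number` effect. Participants observed at fewer than two distinct
#'   cue numbers are dropped with a warning.
#' @export
fit_accuracy_model <- function(trials, reml = TRUE) {
  stopifnot(all(c("participant_id", "cue_number", "correct") %in%
                  names(trials)))
  trials$correct <- as.logical(trials$correct)
  agg <- stats::aggregate(correct ~ participant_id + cue_number,
                          data = trials, FUN = mean)
  names(agg)[names(agg) == "correct"] <- "accuracy"
  n_cues <- vapply(split(agg$cue_number, agg$participant_id),
                   function(v) length(unique(v)), integer(1L))
  bad <- names(n_cues)[n_cues < 2L]
  if (length(bad) > 0L) {
    warning(sprintf("dropping participant(s) with a single cue level: %s",
                    paste(bad, collapse = ", ")))
    agg <- agg[!agg$participant_id %in% bad, , drop = FALSE]
  }
  if (nrow(agg) == 0L) {
    stop_menzerath("model_error", "no participant with >= 2 cue levels")
  }
  agg$participant_id <- factor(agg$participant_id)
  msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(accuracy ~ cue_number + (cue_number | participant_id),
               data = agg, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    }
  )
  fe <- lme4::fixef(model)
  se <- safe_fixef_se(model, length(fe))
  df <- rep(nrow(agg) - length(fe), length(fe))
  df_method <- "residual"
  sdf <- satterthwaite_df(model)
  if (!is.null(sdf) && length(sdf) == length(fe) && all(is.finite(sdf))) {
    df <- as.numeric(sdf)
    df_method <- "satterthwaite"
  }
  tval <- fe / se
  coefs <- data.frame(
    term = names(fe), estimate = as.numeric(fe), se = as.numeric(se),
    t = as.numeric(tval), df = df,
    p = 2 * stats::pt(-abs(as.numeric(tval)), df = df),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  out <- list(
    coefficients = coefs,
    varcomp = data.frame(group = vc$grp, sd = vc$sdcor, variance = vc$vcov,
                         stringsAsFactors = FALSE),
    n_obs = nrow(agg),
    n_sequences = NA_integer_,
    n_individuals = nlevels(agg$participant_id),
    formula = accuracy ~ cue_number + (cue_number | participant_id),
    reml = reml,
    df_method = df_method,
    converged = length(model@optinfo$conv$lme4) == 0L,
    singular = lme4::isSingular(model),
    messages = msgs,
    model = model,
    frame = agg
  )
  class(out) <- "menzerath_fit"
  out
}

#' @export
coef.menzerath_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Wald confidence intervals for the fixed effects
#'
#' @param object A `menzerath_fit`.
#' @param parm Terms to keep (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix with `lower` and `upper` columns.
#' @export
confint.menzerath_fit <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  if (!is.null(parm)) cf <- cf[cf$term %in% parm, , drop = FALSE]
  q <- stats::qt(1 - (1 - level) / 2, df = cf$df)
  out <- cbind(lower = cf$estimate - q * cf$se,
               upper = cf$estimate + q * cf$se)
  rownames(out) <- cf$term
  out
}

#' @export
print.menzerath_fit <- function(x, digits = 4, ...) {
  cat("Menzerath mixed model fit (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  %d observations, %s sequences, %d individuals\n",
              x$n_obs,
              ifelse(is.na(x$n_sequences), "-", x$n_sequences),
              x$n_individuals))
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, digits)
  cf$se <- signif(cf$se, digits)
  cf$t <- signif(cf$t, digits)
  cf$p <- format.pval(cf$p, digits = 3)
  print(cf, row.names = FALSE)
  if (!x$converged) cat("  ** fit did not converge; see $messages **\n")
  invisible(x)
}

#' @export
summary.menzerath_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.menzerath_fit")
}

#' @export
print.summary.menzerath_fit <- function(x, ...) {
  print(x$fit)
  cat("Variance components:\n")
  vc <- x$fit$varcomp
  vc$sd <- signif(vc$sd, 4)
  vc$variance <- signif(vc$variance, 4)
  print(vc, row.names = FALSE)
  cat(sprintf("df method: %s; converged: %s; singular: %s\n",
              x$fit$df_method, x$fit$converged, x$fit$singular))
  if (length(x$fit$messages)) {
    cat("Fitter messages:\n")
    cat(paste(" -", unique(x$fit$messages)), sep = "\n")
  }
  invisible(x)
}

#' Fixed-effect predictions from a Menzerath fit
#'
#' @param object A `menzerath_fit` from [fit_menzerath()].
#' @param newdata Optional data frame with `log_size` and `position` columns
#'   (defaults to the fitting frame).
#' @param ... Unused.
#' @return Predicted log durations from the fixed effects only.
#' @export
predict.menzerath_fit <- function(object, newdata = NULL, ...) {
  cf <- coef(object)
  if (is.null(newdata)) newdata <- object$frame
  if (!all(c("log_size", "position") %in% names(newdata))) {
    stop_menzerath("model_error",
      "newdata must have 'log_size' and 'position' columns")
  }
  cf[["(Intercept)"]] + cf[["log_size"]] * newdata$log_size +
    cf[["position"]] * newdata$position
}

#' @export
residuals.menzerath_fit <- function(object, ...) {
  stats::residuals(object$model)
}
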