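#' Kaplan-Meier curves per group
#'
#' Product-limit estimation via [survival::survfit()]. Curves start at 1
#' and are non-increasing; censored-only times do not change the curve
#' value.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param groups optional group labels (default: one group). Empty groups
#'   are an error.
#' @return named list of `km_curve` objects with `times`, `survival`,
#'   `at_risk`, `n_events`, `group_label`.
#' @export
km_estimate <- function(time, event, groups = NULL) {
  check_surv(time, event)
  if (is.null(groups)) groups <- rep("all", length(time))
  g <- factor(groups)
  if (any(table(g) == 0)) stop("empty group in Kaplan-Meier input")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) factor(rep(levels(g)[1],
                                               length(sm$time)))
            else sm$strata
  out <- lapply(levels(g), function(lev) {
    pick <- grepl(paste0("g=", lev, "$"), as.character(strata)) |
      as.character(strata) == lev
    structure(list(times = sm$time[pick], survival = sm$surv[pick],
                   at_risk = sm$n.risk[pick], n_events = sm$n.event[pick],
                   group_label = lev), class = "km_curve")
  })
  stats::setNames(out, levels(g))
}

#' Export a Kaplan-Meier curve as a step-function table
#' @param curve a `km_curve`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(
    data.frame(group = curve$group_label, time = curve$times,
               survival = curve$survival, at_risk = curve$at_risk,
               n_events = curve$n_events),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group log-rank test
#'
#' Standard log-rank: `chi2 = (sum(O - E))^2 / sum(V)` with the
#' hypergeometric variance at each distinct event time, referred to a
#' 1-df chi-square (via [survival::survdiff()]).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event overall.
#' @param group binary group labels (exactly two non-empty groups).
#' @return list with `chi2`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- factor(group)
  g <- droplevels(g)
  if (nlevels(g) != 2) stop("log-rank test needs exactly two groups")
  if (sum(event) < 1) stop("log-rank test needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Efron-tie partial-likelihood maximisation via [survival::coxph()]
#' (Breslow available), with Wald 95% confidence intervals
#' `exp(beta +/- 1.96 SE)`. Non-convergence or a monotone likelihood
#' (complete separation, flagged by coxph's infinite-coefficient
#' diagnostics or runaway coefficients) is reported through
#' `converged = FALSE` rather than an error; a singular information
#' matrix (aliased covariates) is an error naming the collinear columns.
#' An optional ridge penalty is available as a separation rescue.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param covariates numeric matrix or data frame of covariates (no
#'   constant columns).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param ridge optional ridge penalty (coxph `ridge()` theta); 0 = off.
#' @return a `survival_fit`: `coefficients`, `hr`, `ci95` (matrix
#'   low/high), `wald_p`, `loglik`, `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    ridge = 0) {
  ties <- match.arg(ties)
  check_surv(time, event)
  X <- as.data.frame(covariates)
  if (!ncol(X)) stop("no covariates supplied")
  const <- vapply(X, function(col) length(unique(stats::na.omit(col))) < 2,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(X)[const], collapse = ", "))
  if (sum(event) < ncol(X))
    warning("fewer events (", sum(event), ") than covariates (", ncol(X),
            "); estimates may be unstable")
  dat <- cbind(data.frame(.time = time, .event = event), X)
  rhs <- if (ridge > 0)
    sprintf("ridge(%s, theta = %g)",
            paste(names(X), collapse = ", "), ridge)
  else paste(names(X), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w),
                ignore.case = TRUE))
        warn_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("singular information matrix; collinear covariate(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- !warn_sep && all(abs(beta) < 15)
  structure(list(
    coefficients = beta,
    hr = exp(beta),
    ci95 = cbind(low = exp(beta - 1.96 * se),
                 high = exp(beta + 1.96 * se)),
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = fit$loglik[length(fit$loglik)],
    n = fit$n, n_events = fit$nevent,
    converged = converged),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> n = %d, events = %d, converged: %s\n",
              x$n, x$n_events, x$converged))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    `CI low` = x$ci95[, "low"], `CI high` = x$ci95[, "high"],
                    p = x$wald_p, check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Drop event-free strata before survival modelling
#'
#' Removes samples in strata of `strata_var` with zero events — an
#' explicit, logged preprocessing step that avoids complete separation of
#' stratum indicators in a Cox model.
#'
#' @param data data frame with `time`, `event` and `strata_var` columns.
#' @param strata_var name of the stratum column.
#' @return the filtered data frame; dropped strata are messaged.
#' @export
drop_event_free_strata <- function(data, strata_var) {
  ev <- tapply(data$event, data[[strata_var]], sum)
  dead <- names(ev)[!is.na(ev) & ev == 0]
  if (length(dead)) {
    n_drop <- sum(data[[strata_var]] %in% dead)
    message("dropping ", n_drop, " sample(s) in event-free ",
            strata_var, " strata: ", paste(dead, collapse = ", "))
    data <- data[!data[[strata_var]] %in% dead, , drop = FALSE]
  }
  data
}

check_surv <- function(time, event) {
  if (any(time <= 0, na.rm = TRUE)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}
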