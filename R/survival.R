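# Multivariate Cox proportional hazards models, proportional-hazards
# diagnostics, and Kaplan-Meier / log-rank stratified comparison. Fitting
# goes through the survival package (Efron tie handling); this module owns
# the covariate assembly, the per-SD standardization of the signal, the
# hazard-percent reporting convention, and the family-wise BH adjustment.

#' Fit a multivariate Cox proportional hazards model
#'
#' Conditions the chosen outcome on age, gender, binarized stage and one
#' signal variable (gene expression, module eigengene or %G.A.M.E. score).
#' The signal is standardized to unit SD before fitting, so its coefficient
#' is per standard deviation; hazard_pct = (exp(beta) - 1) * 100 is the
#' percent hazard change per SD. Complete-case per outcome. When all
#' samples fall in one stage group (or one gender), that covariate is
#' dropped with a note.
#'
#' @param clinical a \code{ClinicalTable} data.frame.
#' @param signal named numeric vector of the signal variable (names =
#'   sample ids), or an unnamed vector aligned with \code{clinical}.
#' @param outcome "os" or "dfi".
#' @param covariates covariate columns to condition on.
#' @param signal_name label for the signal row of the coefficient table.
#' @param min_events minimum number of events required (default 10).
#' @return a \code{CoxFit}: list with \code{coefficients} (data.frame term,
#'   beta, se, z, p, hazard_pct), \code{ph_test} (term, rho, p), \code{fit}
#'   (the underlying coxph object), \code{n}, \code{n_events},
#'   \code{loglik}, \code{dropped_covariates}, \code{outcome}.
#' @export
fit_coxph <- function(clinical, signal, outcome = c("os", "dfi"),
                      covariates = c("age", "gender", "stage_binary"),
                      signal_name = "signal", min_events = 10) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical)))
    stop("clinical table lacks ", tcol, "/", ecol)
  df <- as.data.frame(clinical)
  if (!is.null(names(signal))) {
    df$signal <- unname(signal[df$sample_id])
  } else {
    stopifnot(length(signal) == nrow(df))
    df$signal <- signal
  }
  keep_cols <- c(tcol, ecol, intersect(covariates, names(df)), "signal")
  df <- df[stats::complete.cases(df[, keep_cols]), keep_cols, drop = FALSE]
  if (sum(df[[ecol]]) < min_events)
    stop("fewer than ", min_events, " events after complete-case filtering")
  dropped <- character(0)
  use_cov <- intersect(covariates, names(df))
  for (cv in use_cov) {
    if (length(unique(df[[cv]])) < 2) {
      dropped <- c(dropped, cv)
      message("covariate '", cv, "' has a single level; dropped from the model")
    }
  }
  use_cov <- setdiff(use_cov, dropped)
  df$signal <- as.numeric(scale(df$signal))
  fml <- stats::as.formula(paste0("survival::Surv(", tcol, ", ", ecol, ") ~ ",
                                  paste(c(use_cov, "signal"), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 100, eps = 1e-9))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " ")))
    stop("Cox model did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)
  terms[terms == "signal"] <- signal_name
  coefs <- data.frame(term = terms, beta = co[, "coef"], se = co[, "se(coef)"],
                      z = co[, "z"], p = co[, "Pr(>|z|)"],
                      hazard_pct = (exp(co[, "coef"]) - 1) * 100,
                      row.names = NULL, stringsAsFactors = FALSE)
  zp <- tryCatch(survival::cox.zph(fit, transform = "rank"), error = function(e) NULL)
  ph <- if (!is.null(zp)) {
    zt <- zp$table
    zt <- zt[rownames(zt) != "GLOBAL", , drop = FALSE]
    data.frame(term = sub("^signal$", signal_name, rownames(zt)),
               chisq = zt[, "chisq"], p = zt[, "p"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  structure(list(coefficients = coefs, ph_test = ph, fit = fit,
                 n = nrow(df), n_events = sum(df[[ecol]]),
                 loglik = fit$loglik[2], dropped_covariates = dropped,
                 outcome = outcome, signal_name = signal_name),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit [%s]: n = %d, events = %d\n", x$outcome, x$n, x$n_events))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Scaled Schoenfeld residual test of proportional hazards
#'
#' Tests each covariate's scaled Schoenfeld residuals against event-time
#' rank; a small p-value indicates a time-varying effect (violated
#' proportional hazards).
#'
#' @param fit a \code{CoxFit}.
#' @return data.frame: term, chisq, p.
#' @export
schoenfeld_ph_test <- function(fit) {
  stopifnot(inherits(fit, "CoxFit"))
  if (fit$n_events < 2) stop("need >= 2 events for the Schoenfeld test")
  if (is.null(fit$ph_test)) {
    zp <- survival::cox.zph(fit$fit, transform = "rank")
    zt <- zp$table
    zt <- zt[rownames(zt) != "GLOBAL", , drop = FALSE]
    return(data.frame(term = rownames(zt), chisq = zt[, "chisq"], p = zt[, "p"],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  fit$ph_test
}

#' BH-adjust the signal p-values across a family of Cox fits
#'
#' The adjustment family is the set of signal-variable models fitted for
#' one outcome (e.g. gene expression, ME and %G.A.M.E. against OS);
#' covariate p-values within one model are not cross-adjusted.
#'
#' @param fits list of \code{CoxFit} objects for one outcome family.
#' @return data.frame: signal, beta, se, p, p_adj, hazard_pct.
#' @export
adjust_cox_family <- function(fits) {
  rows <- lapply(fits, function(f) {
    r <- f$coefficients[f$coefficients$term == f$signal_name, , drop = FALSE]
    data.frame(signal = f$signal_name, beta = r$beta, se = r$se, p = r$p,
               hazard_pct = r$hazard_pct, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab
}

#' Kaplan-Meier estimate and log-rank test for binarized strata
#'
#' Product-limit survival per group plus the log-rank comparison. The
#' median time-to-event per group is the smallest time at which the
#' survival curve drops to 0.5 or below (NA when never reached).
#'
#' @param time event/censoring times (>= 0).
#' @param event 0/1 event indicators.
#' @param km_labels factor/character group labels (two non-empty groups;
#'   each group needs >= 1 event).
#' @return a \code{KMResult}: list with \code{curves} (data.frame group,
#'   time, n_risk, n_event, surv), \code{medians}, \code{chisq}, \code{p},
#'   \code{group_sizes}.
#' @export
km_estimate <- function(time, event, km_labels) {
  if (any(time < 0)) stop("negative times")
  g <- factor(as.character(km_labels))
  if (nlevels(droplevels(g)) < 2) stop("need two non-empty groups")
  ev_per_group <- tapply(event, g, sum)
  if (any(ev_per_group == 0, na.rm = TRUE))
    stop("log-rank requires >= 1 event in every group")
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  st <- summary(sf, censored = TRUE)
  grp <- sub("^g=", "", as.character(st$strata))
  curves <- data.frame(group = grp, time = st$time, n_risk = st$n.risk,
                       n_event = st$n.event, surv = st$surv,
                       stringsAsFactors = FALSE)
  med <- vapply(split(curves, curves$group), function(cc) {
    below <- cc$time[cc$surv <= 0.5]
    if (length(below)) min(below) else NA_real_
  }, numeric(1))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  structure(list(curves = curves, medians = med, chisq = unname(sd_$chisq),
                 p = p, group_sizes = table(g)),
            class = "KMResult")
}

#' @export
print.KMResult <- function(x, ...) {
  cat(sprintf("KMResult: log-rank chisq = %.3f, p = %.4g\n", x$chisq, x$p))
  print(x$medians)
  invisible(x)
}
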