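#' Build a survival endpoint dataset from clinical records
#'
#' Disease-free survival (DFS): the event is tumour recurrence (local or
#' distant); death without recurrence censors at the death time; otherwise
#' censoring at follow-up. Cancer-specific overall survival (OS): the event is
#' tumour-related death; non-tumour death censors at the death time; animals
#' alive at the end of follow-up are censored there.
#'
#' @param records Clinical data.frame with columns `sample_id`,
#'   `recurrence_months` (NA if none), `death_months` (NA if alive),
#'   `death_cause` (`"tumour"`/`"non_tumour"`/NA).
#' @param endpoint `"DFS"` or `"OS"`.
#' @param followup Administrative follow-up horizon in months (default 24).
#' @return data.frame `sample_id`, `time` (months), `event` (0/1), joined to
#'   all other columns of `records`.
#' @export
build_endpoint <- function(records, endpoint = c("DFS", "OS"), followup = 24) {
  endpoint <- match.arg(endpoint)
  rec <- records$recurrence_months
  dth <- records$death_months
  cause <- records$death_cause
  if (any(!is.na(rec) & !is.na(dth) & dth < rec))
    stop("death before recurrence in record(s)")
  n <- nrow(records)
  time <- numeric(n); event <- integer(n)
  for (i in seq_len(n)) {
    if (endpoint == "DFS") {
      if (!is.na(rec[i]) && rec[i] <= followup) {
        time[i] <- rec[i]; event[i] <- 1L
      } else if (!is.na(dth[i]) && dth[i] <= followup) {
        time[i] <- dth[i]; event[i] <- 0L
      } else {
        time[i] <- followup; event[i] <- 0L
      }
    } else {
      if (!is.na(dth[i]) && dth[i] <= followup &&
          !is.na(cause[i]) && cause[i] == "tumour") {
        time[i] <- dth[i]; event[i] <- 1L
      } else if (!is.na(dth[i]) && dth[i] <= followup) {
        time[i] <- dth[i]; event[i] <- 0L
      } else {
        time[i] <- followup; event[i] <- 0L
      }
    }
  }
  out <- data.frame(sample_id = records$sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(records), c("sample_id", "time", "event"))
  cbind(out, records[, extra, drop = FALSE])
}

#' Kaplan-Meier estimate with restricted mean survival per group
#'
#' Product-limit estimator via [survival::survfit()]; group means are
#' restricted means (area under the KM curve truncated at the largest
#' observed time), the convention behind "mean +/- sem" survival tables.
#'
#' @param dataset Output of [build_endpoint()].
#' @param group_by Optional column name to stratify by.
#' @return List with the `survfit` object (`fit`) and a `means` data.frame
#'   (`group`, `n`, `events`, `rmean`, `se_rmean`).
#' @export
kaplan_meier <- function(dataset, group_by = NULL) {
  if (is.null(group_by)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = dataset)
    groups <- "all"
  } else {
    dataset$..group <- droplevels(as.factor(dataset[[group_by]]))
    if (nlevels(dataset$..group) == 0) stop("empty group")
    fit <- survival::survfit(survival::Surv(time, event) ~ ..group,
                             data = dataset)
    # a single observed level yields an unstratified fit
    groups <- if (is.null(fit$strata)) levels(dataset$..group) else
      sub("^\\.\\.group=", "", names(fit$strata))
  }
  tab <- summary(fit, rmean = max(dataset$time))$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))
  means <- data.frame(group = groups,
                      n = tab[, "records"], events = tab[, "events"],
                      rmean = tab[, "rmean"], se_rmean = tab[, "se(rmean)"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(fit = fit, means = means)
}

#' Mantel-Cox log-rank test
#'
#' K-group log-rank chi-square with hypergeometric variance, p-value from a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param dataset Output of [build_endpoint()].
#' @param group_by Column name defining groups (>= 2 non-empty).
#' @return List `chisq`, `df`, `p`.
#' @export
logrank_test <- function(dataset, group_by) {
  g <- as.factor(dataset[[group_by]])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need >= 2 non-empty groups")
  dataset$..group <- g
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ ..group,
                            data = dataset)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

# likelihood-ratio p-value for adding `term` to formula `base` (coxph, Efron
# ties). Returns NA and a flag when the extended fit fails to converge.
lr_add_p <- function(dataset, base_terms, term) {
  f0 <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                if (length(base_terms)) paste(base_terms, collapse = " + ") else "1"))
  f1 <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(c(base_terms, term), collapse = " + ")))
  fit0 <- survival::coxph(f0, data = dataset, ties = "efron")
  ok <- TRUE
  fit1 <- withCallingHandlers(
    tryCatch(survival::coxph(f1, data = dataset, ties = "efron"),
             error = function(e) { ok <<- FALSE; NULL }),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
        ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!ok || is.null(fit1) || any(!is.finite(stats::coef(fit1))))
    return(list(p = NA_real_, ok = FALSE, fit = NULL))
  df <- length(stats::coef(fit1)) - if (length(base_terms)) length(stats::coef(fit0)) else 0
  lr <- 2 * (fit1$loglik[2] - (if (length(base_terms)) fit0$loglik[2] else fit1$loglik[1]))
  list(p = stats::pchisq(lr, df, lower.tail = FALSE), ok = TRUE, fit = fit1)
}

# LR p-value for dropping `term` from the model containing `terms`
lr_drop_p <- function(dataset, terms, term) {
  keep <- setdiff(terms, term)
  f1 <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(terms, collapse = " + ")))
  f0 <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                if (length(keep)) paste(keep, collapse = " + ") else "1"))
  fit1 <- survival::coxph(f1, data = dataset, ties = "efron")
  ll0 <- if (length(keep)) survival::coxph(f0, data = dataset, ties = "efron")$loglik[2]
         else fit1$loglik[1]
  df <- length(stats::coef(fit1)) -
    (if (length(keep)) length(stats::coef(survival::coxph(f0, data = dataset, ties = "efron"))) else 0)
  lr <- 2 * (fit1$loglik[2] - ll0)
  stats::pchisq(lr, df, lower.tail = FALSE)
}

#' Forward-stepwise Cox proportional-hazards regression
#'
#' At each step the candidate with the smallest likelihood-ratio p-value below
#' `entry` is added (ties broken by covariate name); after every addition, any
#' included covariate whose removal LR p-value exceeds `stay` is removed
#' (worst first). Stops when no addition or removal changes the model.
#' Candidates whose fit does not converge (e.g. complete separation) are
#' flagged and excluded from further consideration. Tied event times use the
#' Efron approximation.
#'
#' @param dataset Output of [build_endpoint()] including covariate columns.
#' @param candidates Character vector of covariate column names.
#' @param entry Entry threshold on the LR p-value (default 0.25).
#' @param stay Retention threshold (default 0.1).
#' @return List: `selected` (character), `fit` (final `coxph` or NULL),
#'   `table` (coef, HR, 95% CI, p per term), `trace` (step log),
#'   `flagged` (non-convergent candidates).
#' @export
cox_forward_stepwise <- function(dataset, candidates, entry = 0.25, stay = 0.1) {
  if (sum(dataset$event) < 1) stop("no events in dataset")
  candidates <- sort(unique(candidates))
  selected <- character(0)
  flagged <- character(0)
  trace <- list()
  seen <- character(0)  # visited model states; stops add/remove cycling
  repeat {
    state <- paste(sort(selected), collapse = "+")
    if (state %in% seen) break
    seen <- c(seen, state)
    pool <- setdiff(candidates, c(selected, flagged))
    changed <- FALSE
    if (length(pool) > 0) {
      ps <- vapply(pool, function(tm) {
        r <- lr_add_p(dataset, selected, tm)
        if (!r$ok) return(NA_real_)
        r$p
      }, numeric(1))
      newly_flagged <- pool[is.na(ps)]
      flagged <- c(flagged, newly_flagged)
      ps <- ps[!is.na(ps)]
      if (length(ps) > 0 && min(ps) < entry) {
        # ties broken by (p, name); pool already name-sorted
        add <- names(ps)[which.min(ps)]
        selected <- c(selected, add)
        trace[[length(trace) + 1]] <- data.frame(step = length(trace) + 1,
                                                 action = "add", term = add,
                                                 p = min(ps))
        changed <- TRUE
      }
    }
    # backward pass: drop covariates no longer retained
    repeat {
      if (length(selected) == 0) break
      dp <- vapply(sort(selected), function(tm) lr_drop_p(dataset, selected, tm),
                   numeric(1))
      if (max(dp) > stay) {
        drop_tm <- names(dp)[which.max(dp)]
        selected <- setdiff(selected, drop_tm)
        trace[[length(trace) + 1]] <- data.frame(step = length(trace) + 1,
                                                 action = "remove",
                                                 term = drop_tm, p = max(dp))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- NULL; tab <- NULL
  if (length(selected) > 0) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sort(selected), collapse = " + ")))
    fit <- survival::coxph(f, data = dataset, ties = "efron")
    ci <- stats::confint(fit)
    sm <- summary(fit)
    tab <- data.frame(term = names(stats::coef(fit)),
                      coef = unname(stats::coef(fit)),
                      hr = unname(exp(stats::coef(fit))),
                      hr_low = unname(exp(ci[, 1])),
                      hr_high = unname(exp(ci[, 2])),
                      p = unname(sm$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(selected = sort(selected), fit = fit, table = tab,
       trace = if (length(trace)) do.call(rbind, trace) else NULL,
       flagged = flagged)
}

#' Cohen's kappa for two labelings
#'
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from marginal products.
#' Returns `NA` (with attribute `undefined = TRUE`) when both raters are
#' constant and identical (`p_e = 1`).
#'
#' @param labels1,labels2 Equal-length vectors over a shared label space.
#' @return Scalar kappa.
#' @export
cohens_kappa <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) stop("unequal lengths")
  lev <- sort(unique(c(as.character(labels1), as.character(labels2))))
  t1 <- factor(labels1, levels = lev); t2 <- factor(labels2, levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(structure(NA_real_, undefined = TRUE))
  (po - pe) / (1 - pe)
}

#' Percent agreement between two labelings, optionally within a stratum
#' @param labels1,labels2 Equal-length vectors.
#' @param stratum Optional logical/index vector selecting the stratum.
#' @return Fraction agreeing in \[0, 1\].
#' @export
percent_agreement <- function(labels1, labels2, stratum = NULL) {
  if (length(labels1) != length(labels2)) stop("unequal lengths")
  if (!is.null(stratum)) {
    labels1 <- labels1[stratum]; labels2 <- labels2[stratum]
  }
  if (length(labels1) == 0) stop("empty stratum")
  mean(labels1 == labels2)
}

#' ROC-based cutoff maximizing Youden's J
#'
#' Enumerates all observed score values as candidate cutoffs for the rule
#' "score >= cutoff predicts positive" (and the complementary "<=" rule) and
#' returns the cutoff maximizing J = sensitivity + specificity - 1. Ties go to
#' the lower cutoff; the ">=" direction wins direction ties.
#'
#' @param scores Numeric scores.
#' @param outcome Binary outcome (0/1 or logical), both classes present.
#' @return List `cutoff`, `direction` (`">="` or `"<="`), `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
roc_cutoff <- function(scores, outcome) {
  outcome <- as.integer(as.logical(outcome))
  if (length(unique(outcome)) < 2) stop("both outcome classes required")
  cuts <- sort(unique(scores))
  pos <- outcome == 1
  eval_rule <- function(pred) {
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }
  best <- NULL
  for (dir in c(">=", "<=")) {
    for (ct in cuts) {
      pred <- if (dir == ">=") scores >= ct else scores <= ct
      st <- eval_rule(pred)
      if (is.null(best) || st["j"] > best$youden_j + 1e-12) {
        best <- list(cutoff = ct, direction = dir, youden_j = unname(st["j"]),
                     sensitivity = unname(st["sens"]),
                     specificity = unname(st["spec"]))
      }
    }
  }
  best
}
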