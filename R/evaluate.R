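#' ROC AUC with DeLong confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with tie correction, a 95%
#' DeLong confidence interval, and a two-sided Wilcoxon rank-sum p-value
#' comparing the scores of the two classes.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`, `p`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))  # degenerate at AUC 1
  p <- suppressWarnings(
    stats::wilcox.test(scores[labels == 1], scores[labels == 0])$p.value)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3], p = p,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g (%d pos / %d neg)\n",
              x$auc, x$ci_low, x$ci_high, x$p, x$n_pos, x$n_neg))
  invisible(x)
}

check_cohort <- function(cohort) {
  need <- c("time", "event")
  if (!all(need %in% names(cohort))) stop("cohort needs time and event columns")
  if (anyNA(cohort$time) || anyNA(cohort$event))
    stop("missing time/event values in cohort")
  if (any(cohort$time <= 0)) stop("survival times must be positive")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(cohort)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param cohort data.frame with `time` and `event` columns.
#' @param labels grouping vector aligned with the cohort rows.
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, and `p` (log-rank).
#' @export
km_logrank <- function(cohort, labels) {
  check_cohort(cohort)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("both label groups must be nonempty")
  df <- data.frame(time = cohort$time, event = cohort$event, group = labels)
  if (any(tapply(df$event, df$group, sum) == 0))
    warning("a group has zero events; log-rank statistic may be unstable")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit)
  curves <- data.frame(group = sub("^group=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  list(curves = curves, chisq = sd$chisq, p = p)
}

#' Cox proportional hazards model (univariate or multivariate)
#'
#' Partial-likelihood fit over the named cohort columns; hazard ratios with
#' 95% confidence intervals per term. Warns when there are fewer than 10
#' events per fitted coefficient.
#'
#' @param cohort data.frame with `time`, `event`, and the term columns.
#' @param terms character vector of column names to fit (one for
#'   univariate, several for multivariate).
#' @return data.frame of class `cox_result`: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
cox_model <- function(cohort, terms) {
  check_cohort(cohort)
  missing <- setdiff(terms, names(cohort))
  if (length(missing) > 0)
    stop("term(s) not in cohort: ", paste(missing, collapse = ", "))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = cohort)
  if (any(is.na(stats::coef(fit))))
    stop("Cox model did not converge (NA coefficients); check collinearity")
  if (sum(cohort$event) < 10 * length(stats::coef(fit)))
    warning("fewer than 10 events per fitted coefficient")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Survival-based score cutoff optimization
#'
#' Scans the observed score values as candidate cutoffs, keeping those that
#' leave at least `min_group_frac` of the samples on each side, and returns
#' the cutoff minimizing the two-group log-rank p-value together with the
#' full cutoff-vs-p profile. The minimized p-value is descriptive only: the
#' scan optimizes over cutoffs, so it is biased low and must not be read as
#' a hypothesis test.
#'
#' @param scores named numeric scores; names must match `cohort$sample` (or
#'   row order when the cohort has no `sample` column).
#' @param cohort data.frame with `time`, `event` (and optionally `sample`).
#' @param min_group_frac minimum fraction of samples per side.
#' @param min_samples minimum cohort size.
#' @return list with `cutoff`, `p` (the minimized log-rank p, descriptive),
#'   and `profile` (data.frame: `cutoff`, `n_low`, `n_high`, `p`).
#' @export
survival_cutoff_optimize <- function(scores, cohort, min_group_frac = 0.1,
                                     min_samples = 30) {
  check_cohort(cohort)
  if ("sample" %in% names(cohort) && !is.null(names(scores))) {
    scores <- scores[match(cohort$sample, names(scores))]
    if (anyNA(scores)) stop("scores missing for some cohort samples")
  }
  n <- nrow(cohort)
  if (n < min_samples) stop("need at least ", min_samples, " samples")
  s <- as.numeric(scores)
  cand <- sort(unique(s))
  n_low <- vapply(cand, function(c) sum(s <= c), numeric(1))
  ok <- n_low >= min_group_frac * n & (n - n_low) >= min_group_frac * n
  if (!any(ok)) stop("no admissible cutoff at min_group_frac = ", min_group_frac)
  cand <- cand[ok]
  prof <- lapply(cand, function(cut) {
    grp <- factor(ifelse(s > cut, "high", "low"), levels = c("low", "high"))
    sd <- survival::survdiff(
      survival::Surv(cohort$time, cohort$event) ~ grp)
    data.frame(cutoff = cut, n_low = sum(grp == "low"),
               n_high = sum(grp == "high"),
               p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  })
  prof <- do.call(rbind, prof)
  best <- which.min(prof$p)
  list(cutoff = prof$cutoff[best], p = prof$p[best], profile = prof)
}

#' Signature-drug-response screen
#'
#' Per compound, the Spearman correlation between the per-line signature
#' score and the viability log-fold-change over the lines with both values,
#' with BH adjustment across compounds. A negative rho means higher-scoring
#' lines lose more viability — a sensitivity association.
#'
#' @param score_by_line named numeric per-line scores.
#' @param lfc lines x compounds LFC matrix (NAs allowed); rownames must
#'   match the score names.
#' @param min_lines minimum complete lines per compound; compounds below
#'   are dropped with a warning.
#' @param fdr FDR level used for the `sensitive` flag.
#' @return data.frame: `compound`, `n`, `rho`, `p`, `q`, `sensitive`
#'   (`rho < 0 & q <= fdr`), ordered by `p`.
#' @export
drug_screen <- function(score_by_line, lfc, min_lines = 10, fdr = 0.05) {
  lines <- intersect(names(score_by_line), rownames(lfc))
  if (length(lines) < min_lines)
    stop("fewer than ", min_lines, " lines with both score and LFC")
  s <- as.numeric(score_by_line[lines])
  rows <- lapply(colnames(lfc), function(cmpd) {
    v <- lfc[lines, cmpd]
    ok <- !is.na(v)
    if (sum(ok) < min_lines) return(NULL)
    ct <- suppressWarnings(stats::cor.test(s[ok], v[ok], method = "spearman"))
    data.frame(compound = cmpd, n = sum(ok),
               rho = unname(ct$estimate), p = ct$p.value)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " compound(s) dropped: fewer than ", min_lines,
            " complete lines")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no compound with enough complete lines")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$sensitive <- out$rho < 0 & out$q <= fdr
  out[order(out$p, out$compound), , drop = FALSE]
}
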