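#' Join PEP clusters with survival records and keep the major clusters
#'
#' Merges a PEP table with survival outcomes by sample ID, pools stages
#' into period clusters, and retains the clusters with strictly more than
#' `min_n` members. The reference cluster is always retained when
#' nonempty, regardless of size, because hazard ratios are expressed
#' against it.
#'
#' @param pep a [assign_pep()] result (or data.frame with `sample`,
#'   `pep_hours`).
#' @param surv data.frame with `sample`, `time_months`, `event`.
#' @param min_n strict minimum cluster size (default 10: clusters of
#'   exactly `min_n` are dropped).
#' @param reference reference cluster label (default `"h0-8"`).
#' @param breaks,labels passed to [pep_clusters()].
#' @return data.frame with `sample`, `time_months`, `event`, `group`;
#'   attribute `dropped` counts excluded samples.
#' @export
filter_major_clusters <- function(pep, surv, min_n = 10L,
                                  reference = "h0-8",
                                  breaks = c(8, 24, 72, 168),
                                  labels = c("h0-8", "h16-24", "h72", "h168", "h>168")) {
  merged <- merge(pep[, c("sample", "pep_hours")], surv, by = "sample")
  merged <- merged[!is.na(merged$pep_hours), ]
  if (any(!is.finite(merged$time_months)) || any(merged$time_months <= 0))
    abort_field("surv", "times must be finite and positive")
  if (!all(merged$event %in% c(0L, 1L)))
    abort_field("surv", "event flags must be 0 or 1")
  merged$group <- pep_clusters(merged$pep_hours, breaks, labels)
  sizes <- table(merged$group)
  keep <- names(sizes)[sizes > min_n]
  if (reference %in% names(sizes)) keep <- union(keep, reference)
  dropped <- sum(!(merged$group %in% keep))
  if (dropped > 0)
    message(sprintf("dropping %d sample(s) in minor PEP clusters (size <= %d)",
                    dropped, min_n))
  out <- merged[merged$group %in% keep, c("sample", "time_months", "event", "group")]
  if (length(unique(out$group)) < 2L)
    stop("fewer than 2 PEP clusters retained; survival comparison impossible",
         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct event times of the group; censored-only times reduce the
#' at-risk count without dropping the curve.
#'
#' @param data data.frame with `time_months`, `event` (and optionally
#'   `group`).
#' @param group if given, restrict to this value of `data$group`.
#' @return data.frame: `time`, `n_risk`, `n_event`, `surv` (rows at the
#'   distinct observed times).
#' @export
km_estimator <- function(data, group = NULL) {
  if (!is.null(group)) data <- data[data$group == group, ]
  if (nrow(data) == 0L) abort_field("group", "no samples in group")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = data)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' K-sample log-rank test across PEP clusters
#'
#' Observed-versus-expected event counts per group under the
#' hypergeometric margins at each distinct event time; the statistic is
#' chi-squared with `k - 1` degrees of freedom.
#'
#' @param data data.frame with `time_months`, `event`, `group`.
#' @return List: `statistic`, `df`, `p_value`, `observed`, `expected`
#'   (per group).
#' @export
logrank_test <- function(data) {
  grp <- factor(data$group)
  if (nlevels(grp) < 2L) abort_field("data", "log-rank needs >= 2 groups")
  sd_fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = data)
  df <- length(sd_fit$n) - 1L
  list(statistic = unname(sd_fit$chisq), df = df,
       p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       observed = sd_fit$obs, expected = sd_fit$exp)
}

#' Cox proportional-hazards ratios against a reference cluster
#'
#' Partial-likelihood fit with group indicator covariates (reference
#' omitted) and Breslow tie handling. Hazard ratios, Wald 95% confidence
#' intervals and p-values are reported per non-reference group; the
#' reference has HR 1 by construction. Monotone-likelihood fits (e.g. a
#' group without events) are flagged.
#'
#' @param data data.frame with `time_months`, `event`, `group`.
#' @param reference reference group label.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame: `group`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `flagged`.
#' @export
cox_hazard_ratios <- function(data, reference, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!reference %in% data$group)
    abort_field("reference", "not present in the data")
  data$group <- stats::relevel(factor(data$group), ref = reference)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time_months, event) ~ group,
                    data = data, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time_months, event) ~ group,
                        data = data, ties = ties))
      attr(f, "flagged") <- TRUE
      f
    })
  flagged <- isTRUE(attr(fit, "flagged")) ||
    any(!is.finite(sqrt(diag(fit$var)))) || any(abs(stats::coef(fit)) > 15)
  if (flagged)
    warning("Cox fit flagged: monotone likelihood or non-convergence; boundary HRs reported")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  lv <- levels(data$group)[-1]
  out <- data.frame(group = c(reference, lv),
                    hr = c(1, exp(beta)),
                    ci_lower = c(NA, exp(beta - 1.96 * se)),
                    ci_upper = c(NA, exp(beta + 1.96 * se)),
                    p_value = c(NA, 2 * stats::pnorm(-abs(beta / se))),
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
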