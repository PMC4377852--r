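# Survival machinery: optimal marker cutpoints with minimal-p correction,
# Harrell's concordance index, and Kaplan-Meier / log-rank / Cox contracts.

# Vectorized two-group log-rank chi-square statistics for a scan over
# candidate cutpoints of one marker. For each cutpoint the "high" group is
# marker > cutpoint. Handles tied event times; O(n) per cutpoint after one
# sort.
logrank_scan <- function(marker, time, event, cutpoints) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; m_s <- marker[ord]
  n <- length(t_s)
  # tie blocks of identical times; per-block sums via reverse cumsums
  first <- which(!duplicated(t_s))
  block_sum <- function(x) {
    rc <- revcumsum(x)[first]
    rc - c(rc[-1L], 0)
  }
  d <- block_sum(e_s)                      # events per block
  n_risk <- n - first + 1                  # at risk at each block
  ev_blocks <- which(d > 0)

  chisq <- numeric(length(cutpoints))
  for (ci in seq_along(cutpoints)) {
    g <- m_s > cutpoints[ci]
    n1 <- revcumsum(as.numeric(g))[first]  # high-group at risk per block
    d1 <- block_sum(e_s * g)
    nb <- n_risk[ev_blocks]; n1b <- n1[ev_blocks]
    db <- d[ev_blocks]; d1b <- d1[ev_blocks]
    u <- sum(d1b - db * n1b / nb)
    ok <- nb > 1
    v <- sum((db * (n1b / nb) * (1 - n1b / nb) * (nb - db) / (nb - 1))[ok])
    chisq[ci] <- if (v > 0) u^2 / v else 0
  }
  chisq
}

#' Minimal-p correction for an optimized cutpoint
#'
#' Corrects the minimal log-rank p-value obtained by scanning cutpoints over
#' the inner `(eps, 1 - eps)` span of the marker distribution, using the
#' Miller-Siegmund approximation adopted by Altman and colleagues:
#' `p_cor = phi(z) (z - 1/z) log((1 - eps)^2 / eps^2) + 4 phi(z) / z`
#' with `z` the standard-normal quantile of `p_min / 2`. The corrected value
#' is clamped to `[p_min, 1]`, hence never smaller than the uncorrected one.
#'
#' @param p_min minimal (uncorrected) p-value from the scan.
#' @param eps selection fraction on each side (default 0.1, the inner 80%).
#' @return corrected p-value.
#' @export
correct_minimum_p <- function(p_min, eps = 0.1) {
  z <- stats::qnorm(1 - p_min / 2)
  p_cor <- ifelse(z <= 1,
                  1,
                  stats::dnorm(z) * (z - 1 / z) * log((1 - eps)^2 / eps^2) +
                    4 * stats::dnorm(z) / z)
  pmin(pmax(p_cor, p_min), 1)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher risk score has
#' the shorter survival; ties in score count one half. A pair is comparable
#' when the earlier time is an observed event and the times differ.
#'
#' @param score risk scores (higher = higher risk).
#' @param time,event survival times and event indicators (1 = event).
#' @return concordance in `[0, 1]`.
#' @export
harrell_c <- function(score, time, event) {
  n <- length(score)
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(event, n, n)
  si <- matrix(score, n, n); sj <- t(si)
  comparable <- (ti < tj & ei == 1)
  n_comp <- sum(comparable)
  if (n_comp == 0L) stop("no comparable pairs")
  conc <- sum(comparable & si > sj)
  ties <- sum(comparable & si == sj)
  (conc + 0.5 * ties) / n_comp
}

#' Optimal survival cutpoint within the inner 80% of a marker
#'
#' Candidate cutpoints are the midpoints between consecutive distinct marker
#' values whose low-side fraction lies within `[eps, 1 - eps]` (default the
#' inner 80% selection interval). Under `criterion = "min_p"` the cutpoint
#' minimizing the two-group log-rank p-value is chosen and the minimal p is
#' corrected with [correct_minimum_p()]; under `criterion = "max_c"` the
#' cutpoint maximizing Harrell's C of the dichotomized marker is chosen.
#'
#' @param marker numeric marker values.
#' @param time,event survival data.
#' @param criterion `"min_p"` or `"max_c"`.
#' @param eps selection fraction (default 0.1).
#' @return list with `cutpoint`, `p_uncorrected`, `p_corrected`,
#'   `harrell_c`, `n_low`, `n_high` and the `candidates` scanned.
#' @export
optimal_cutpoint <- function(marker, time, event,
                             criterion = c("min_p", "max_c"), eps = 0.1) {
  criterion <- match.arg(criterion)
  n <- length(marker)
  if (n < 10L) stop("need >= 10 patients")
  if (sum(event) == 0L) stop("no events observed")
  if (length(unique(marker)) < 2L) stop("all marker values identical")

  s <- sort(marker)
  distinct <- which(diff(s) > 0)
  frac_low <- distinct / n
  keep <- frac_low >= eps & frac_low <= 1 - eps
  if (!any(keep))
    stop("no candidate cutpoints inside the inner selection interval")
  cand <- (s[distinct[keep]] + s[distinct[keep] + 1L]) / 2

  if (criterion == "min_p") {
    chisq <- logrank_scan(marker, time, event, cand)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    best <- which.min(p)
    cut <- cand[best]
    p_min <- p[best]
  } else {
    cvals <- vapply(cand, function(cc)
      harrell_c(as.numeric(marker > cc), time, event), numeric(1))
    best <- which.max(cvals)
    cut <- cand[best]
    chisq <- logrank_scan(marker, time, event, cut)
    p_min <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(cutpoint = cut,
       p_uncorrected = p_min,
       p_corrected = correct_minimum_p(p_min, eps = eps),
       harrell_c = harrell_c(as.numeric(marker > cut), time, event),
       n_low = sum(marker <= cut), n_high = sum(marker > cut),
       candidates = cand)
}

#' Kaplan-Meier curves, log-rank test and hazard ratio for two groups
#'
#' @param group named or plain vector with levels `"lo"`/`"hi"` (or any two
#'   levels; the second sorted level is treated as "high").
#' @param time,event survival data aligned with `group`.
#' @return list with `km` (data frame `group`, `time`, `surv`), `logrank_p`,
#'   `hr` (hazard ratio of the high vs low group from a univariate Cox fit)
#'   and `hr_ci` (95% confidence interval).
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L))
    stop("need two non-empty groups")
  if (setequal(levels(group), c("lo", "hi")))
    group <- factor(group, levels = c("lo", "hi"))
  if (sum(event) == 0L)
    stop("no events observed: survival comparison undefined (all censored)")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, surv = sf$surv)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group)
  hr <- unname(exp(stats::coef(cx)))
  ci <- exp(stats::confint(cx))
  list(km = km, logrank_p = logrank_p, hr = hr,
       hr_ci = c(lower = ci[1L], upper = ci[2L]))
}
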