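#' Protein-normalized phosphosite abundance
#'
#' Normalizes each patient's phosphosite abundance to the protein abundance
#' by subtraction on the log scale; patients lacking either value are dropped
#' and listed in the `dropped` attribute.
#'
#' @param records Data frame with `patient_id`, `phospho_abundance`,
#'   `protein_abundance` (log scale).
#' @return Data frame `patient_id`, `normalized`.
#' @export
normalize_phospho <- function(records) {
  if (nrow(records) == 0) {
    out <- data.frame(patient_id = character(0), normalized = numeric(0))
    attr(out, "dropped") <- character(0)
    return(out)
  }
  ok <- is.finite(records$phospho_abundance) &
    is.finite(records$protein_abundance)
  out <- data.frame(patient_id = records$patient_id[ok],
                    normalized = records$phospho_abundance[ok] -
                      records$protein_abundance[ok],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- records$patient_id[!ok]
  out
}

#' Select the extreme abundance groups
#'
#' Returns the `k` patients with the highest and the `k` with the lowest
#' values. Ties at either boundary are broken by patient id
#' (lexicographically) so the selection is deterministic.
#'
#' @param values Data frame from [normalize_phospho()] (or any data frame
#'   with `patient_id` and a value column named `normalized`).
#' @param k Group size (default 20, top 20 versus lowest 20).
#' @return List with `high` and `low` character vectors of patient ids.
#' @export
select_extreme_groups <- function(values, k = 20) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  n <- nrow(values)
  if (n < 2 * k) {
    stop(sprintf("insufficient cohort: %d patients for two groups of %d",
                 n, k), call. = FALSE)
  }
  ord <- order(values$normalized, values$patient_id)
  list(high = values$patient_id[rev(ord)[seq_len(k)]],
       low = values$patient_id[ord[seq_len(k)]])
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t)` is the product over event times up to `t` of `(1 - d_i / n_i)`;
#' censored records leave the risk set without producing a step.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return A `km_curve` data frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, beginning at `S(0) = 1`.
#' @export
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 0))
kaplan_meier <- function(times, events) {
  if (any(!is.finite(times) | times < 0)) {
    stop("follow-up times must be non-negative", call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = c(0, sf$time),
                    n_risk = c(length(times), sf$n.risk),
                    n_event = c(0, sf$n.event),
                    n_censor = c(0, sf$n.censor),
                    survival = c(1, sf$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank: at each event time the observed event count
#' per group is compared with its hypergeometric expectation given the risk
#' sets; the statistic `(sum(O - E))^2 / sum(V)` is referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param group_a,group_b Data frames with columns `followup_time` and
#'   `event`.
#' @return A `logrank_test` list: `statistic`, `p_value`, `df`, `n`,
#'   `observed`, `expected`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(group_a$followup_time, group_b$followup_time)
  event <- c(group_a$event, group_b$event)
  if (sum(event) == 0) {
    stop("log-rank test undefined: no events observed", call. = FALSE)
  }
  grp <- factor(rep(c("A", "B"), c(nrow(group_a), nrow(group_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd$chisq)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L,
                 n = c(A = nrow(group_a), B = nrow(group_b)),
                 observed = unname(sd$obs), expected = unname(sd$exp)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f (1 df), p = %.4g; n = %d vs %d\n",
              x$statistic, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}
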