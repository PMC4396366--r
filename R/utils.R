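#' @keywords internal
"_PACKAGE"

# SILAC channel-pair labels, in the column order used throughout.
RATIO_PAIRS <- c("H/L", "M/L", "H/M")

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_CHAR <- "_"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_range <- function(cfg, field, lower = -Inf, upper = Inf,
                        lower_open = FALSE, upper_open = FALSE,
                        integer = FALSE) {
  x <- cfg[[field]]
  if (is.null(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (integer && x != round(x)) stop_config(field, "must be an integer")
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_config(field, sprintf("must lie in %s%s, %s%s",
                               if (lower_open) "(" else "[", lower,
                               upper, if (upper_open) ")" else "]"))
  }
  invisible(TRUE)
}

#' Column name for a SILAC ratio
#'
#' Replicate-level columns are named `"Ratio <pair> Exp<n> R<r>"`; replicate-
#' merged columns drop the `R<r>` suffix.
#'
#' @param experiment Experiment number (1-4).
#' @param pair Channel pair, one of `"H/L"`, `"M/L"`, `"H/M"`.
#' @param replicate Replicate index, or `NULL` for a merged column.
#' @return A column name string.
#' @export
ratio_column <- function(experiment, pair, replicate = NULL) {
  stopifnot(pair %in% RATIO_PAIRS)
  base <- sprintf("Ratio %s Exp%d", pair, as.integer(experiment))
  if (is.null(replicate)) base else sprintf("%s R%d", base, as.integer(replicate))
}

#' Derive a stage-specific seed from a global seed
#'
#' A fixed multiplicative hash of the stage name keeps downstream stages
#' rerunnable in isolation while fanning out a single user-facing seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name string.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629) + 1L
}
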