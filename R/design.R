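#' Default triple-SILAC experiment design
#'
#' Four 'double-triple' SILAC mixes spanning the screen's conditions.
#' Experiment 1 compares unstimulated cells (light) with cells treated with a
#' selective kinase inhibitor (middle) or with TNF-alpha (heavy). Experiment 2
#' adds the inhibitor-before-stimulus arm, and experiments 3 and 4 overexpress
#' the wild-type or the kinase-dead mutant kinase, in each case with the
#' TNF-alpha-stimulated population as the common reference channel (middle).
#'
#' @return A named list with one element per experiment (`"1"`..`"4"`), each a
#'   named character vector mapping channels `L`, `M`, `H` to condition names,
#'   with a `"reference"` attribute naming the reference channel for
#'   experiments 2-4.
#' @export
#' @examples
#' default_experiment_design()
default_experiment_design <- function() {
  d <- list(
    `1` = c(L = "control",   M = "inhibitor", H = "tnf"),
    `2` = c(L = "control",   M = "tnf",       H = "tnf_inhibitor"),
    `3` = c(L = "ikk_wt",    M = "tnf",       H = "tnf_ikk_wt"),
    `4` = c(L = "ikk_kd",    M = "tnf",       H = "tnf_ikk_kd")
  )
  attr(d, "reference") <- c(`2` = "M", `3` = "M", `4` = "M")
  class(d) <- "experiment_design"
  d
}

validate_design <- function(design) {
  if (!is.list(design) || !all(c("1", "2", "3", "4") %in% names(design))) {
    stop("experiment design must map experiments 1-4", call. = FALSE)
  }
  for (e in c("1", "2", "3", "4")) {
    ch <- design[[e]]
    if (length(ch) != 3L || !all(c("L", "M", "H") %in% names(ch))) {
      stop(sprintf("experiment %s must map exactly the three channels L, M, H", e),
           call. = FALSE)
    }
  }
  invisible(design)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Triple-SILAC experiment design\n")
  for (e in names(x)[names(x) %in% c("1", "2", "3", "4")]) {
    cat(sprintf("  Exp %s: L=%s, M=%s, H=%s\n",
                e, x[[e]]["L"], x[[e]]["M"], x[[e]]["H"]))
  }
  invisible(x)
}

# All condition names used by the generative model.
design_conditions <- function(design) unique(unlist(design[c("1", "2", "3", "4")]))
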