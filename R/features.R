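#' Build a position-specific scoring matrix from positive windows
#'
#' Per-position residue probabilities are `(count + pseudocount) /
#' (n + pseudocount * |alphabet|)` over the alphabet of 20 amino acids plus
#' the terminal pad character, converted to log2 odds against the background.
#'
#' @param windows Character vector of 31-residue training windows.
#' @param pseudocount Additive pseudocount (> 0 keeps all entries finite).
#' @param background Named background frequencies; entries missing from the
#'   alphabet default to 1/20 (amino acids) and `min(background)` (pad).
#' @return A `pssm` object: 31 x 21 log-odds `matrix`, plus the background,
#'   pseudocount and training-set size.
#' @export
build_pssm <- function(windows, pseudocount = 1, background = NULL) {
  if (length(windows) < 1) stop("at least one training window required",
                                call. = FALSE)
  bad <- nchar(windows) != 31
  if (any(bad)) {
    stop(sprintf("training window of wrong length: '%s'", windows[which(bad)[1]]),
         call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  alphabet <- c(AA_ALPHABET, PAD_CHAR)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 21), alphabet)
  } else {
    bg <- stats::setNames(rep(NA_real_, 21), alphabet)
    bg[names(background)] <- background
    bg[AA_ALPHABET][is.na(bg[AA_ALPHABET])] <- 1 / 20
    if (is.na(bg[PAD_CHAR])) bg[PAD_CHAR] <- min(bg, na.rm = TRUE)
    background <- bg
  }

  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  chars[!chars %in% alphabet] <- PAD_CHAR
  counts <- vapply(seq_len(31), function(p) {
    tabulate(factor(chars[, p], levels = alphabet), nbins = 21)
  }, numeric(21))
  counts <- t(counts)  # 31 positions x 21 letters
  colnames(counts) <- alphabet
  rownames(counts) <- sprintf("p%02d", seq_len(31))

  p <- (counts + pseudocount) / (length(windows) + pseudocount * 21)
  logodds <- log2(sweep(p, 2, background[alphabet], `/`))
  structure(list(matrix = logodds, probabilities = p,
                 background = background[alphabet],
                 pseudocount = pseudocount, n_windows = length(windows)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: 31 x %d log2-odds matrix trained on %d windows (pseudocount %g)\n",
              ncol(x$matrix), x$n_windows, x$pseudocount))
  invisible(x)
}

#' Background residue frequencies over a window set
#' @param windows Character vector of 31-residue windows.
#' @param pseudocount Additive pseudocount per alphabet letter.
#' @return Named frequency vector over the 21-letter alphabet.
#' @export
window_background <- function(windows, pseudocount = 1) {
  alphabet <- c(AA_ALPHABET, PAD_CHAR)
  chars <- unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE)
  chars[!chars %in% alphabet] <- PAD_CHAR
  counts <- tabulate(factor(chars, levels = alphabet), nbins = 21) + pseudocount
  stats::setNames(counts / sum(counts), alphabet)
}

#' Score a window against a PSSM
#'
#' Scoring is position-local: position `i` contributes
#' `pssm$matrix[i, window[i]]`. Characters outside the alphabet are treated
#' as the pad character.
#'
#' @param pssm A [build_pssm()] object.
#' @param window A 31-residue window.
#' @return List with `scores` (named numeric, one per position) and `total`
#'   (their sum).
#' @export
score_window <- function(pssm, window) {
  if (nchar(window) != 31) stop("window must have 31 residues", call. = FALSE)
  s <- score_windows(pssm, window)[1, ]
  list(scores = s, total = sum(s))
}

#' Score many windows against a PSSM
#' @param pssm A [build_pssm()] object.
#' @param windows Character vector of 31-residue windows.
#' @return Numeric matrix, one row per window, one column per position.
#' @export
score_windows <- function(pssm, windows) {
  alphabet <- colnames(pssm$matrix)
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  chars[!chars %in% alphabet] <- PAD_CHAR
  idx <- matrix(match(chars, alphabet), nrow = length(windows))
  out <- vapply(seq_len(31), function(p) pssm$matrix[p, idx[, p]],
                numeric(length(windows)))
  out <- matrix(out, nrow = length(windows))
  colnames(out) <- rownames(pssm$matrix)
  rownames(out) <- NULL
  out
}

#' Write / read a PSSM as TSV with '#' metadata header lines
#' @param pssm A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pseudocount\t%.17g", pssm$pseudocount),
               sprintf("# n_windows\t%d", pssm$n_windows),
               sprintf("# background\t%s",
                       paste(sprintf("%s=%.17g", names(pssm$background),
                                     pssm$background), collapse = ","))),
             con)
  utils::write.table(cbind(position = rownames(pssm$matrix),
                           as.data.frame(pssm$matrix, check.names = FALSE)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Feature-name blocks of a feature matrix.
BASE_FEATURES <- sprintf("l2r_e%d_%s", rep(1:4, each = 3),
                         rep(c("HL", "ML", "HM"), 4))
DERIVED_FEATURES <- c("kinase_basal", "wt_vs_kd_tnf", "kd_vs_tnf")

#' Build the per-site classification feature matrix
#'
#' Combines, per site: the 12 log2 SILAC ratios (3 channel pairs x 4
#' experiments, replicate-merged), three derived kinase-dependence contrasts
#' - `kinase_basal`: overexpressed kinase without stimulation versus the
#'   stimulated reference (`-log2(M/L)`, experiment 3),
#' - `wt_vs_kd_tnf`: wild-type versus kinase-dead effect under stimulation
#'   (`log2(H/M)` exp 3 minus `log2(H/M)` exp 4),
#' - `kd_vs_tnf`: kinase-dead arm versus stimulus alone (`log2(H/M)`, exp 4) -
#' and 31 per-position sequence scores under each classifier's PSSM. The
#' complete-case mask is true only for sites with all 12 base ratios present.
#'
#' @param table Replicate-merged `site_table`.
#' @param pssm_ikk PSSM trained on the kinase-substrate positive set.
#' @param pssm_tnf PSSM trained on the stimulus-responder positive set.
#' @return A `feature_matrix` data frame keyed by `site_id` with a
#'   `complete_case` column; feature blocks are recorded in the
#'   `feature_blocks` attribute.
#' @export
build_feature_matrix <- function(table, pssm_ikk, pssm_tnf) {
  design <- attr(table, "design")
  if (is.null(design)) stop("site table carries no experiment design",
                            call. = FALSE)
  df <- as.data.frame(table)
  fm <- data.frame(site_id = df$site_id, stringsAsFactors = FALSE)
  for (e in 1:4) {
    for (pair in RATIO_PAIRS) {
      col <- ratio_column(e, pair)
      if (!col %in% names(df)) {
        stop(sprintf("merged ratio column '%s' missing; merge replicates first",
                     col), call. = FALSE)
      }
      fm[[sprintf("l2r_e%d_%s", e, gsub("/", "", pair))]] <- log2(df[[col]])
    }
  }
  fm$kinase_basal <- -fm$l2r_e3_ML
  fm$wt_vs_kd_tnf <- fm$l2r_e3_HM - fm$l2r_e4_HM
  fm$kd_vs_tnf <- fm$l2r_e4_HM

  seq_ikk <- score_windows(pssm_ikk, df$window)
  seq_tnf <- score_windows(pssm_tnf, df$window)
  colnames(seq_ikk) <- paste0("seq_ikk_", colnames(seq_ikk))
  colnames(seq_tnf) <- paste0("seq_tnf_", colnames(seq_tnf))
  fm <- cbind(fm, as.data.frame(seq_ikk), as.data.frame(seq_tnf))

  fm$complete_case <- rowSums(!is.finite(as.matrix(fm[BASE_FEATURES]))) == 0
  attr(fm, "feature_blocks") <- list(
    base = c(BASE_FEATURES, DERIVED_FEATURES),
    seq_ikk = colnames(seq_ikk),
    seq_tnf = colnames(seq_tnf))
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature manifest for one classifier
#'
#' The kinase classifier sees the ratio-type features plus its own sequence
#' block; likewise the stimulus classifier.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param classifier `"ikk"` or `"tnf"`.
#' @return Character vector of feature column names.
#' @export
feature_manifest <- function(fm, classifier = c("ikk", "tnf")) {
  classifier <- match.arg(classifier)
  blocks <- attr(fm, "feature_blocks")
  c(blocks$base, blocks[[paste0("seq_", classifier)]])
}
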