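#' Default column map for site tables
#'
#' Maps the package's internal field names to the header names of the
#' MaxQuant-style phosphosite table dialect it reads and writes. Override
#' entries to absorb header drift across upstream software versions.
#'
#' @return Named character vector `internal field -> file column`.
#' @export
default_column_map <- function() {
  c(site_id = "id",
    protein = "Proteins",
    gene = "Gene names",
    position = "Position",
    residue = "Amino acid",
    window = "Sequence window",
    localization_prob = "Localization prob",
    is_reverse = "Reverse",
    is_contaminant = "Potential contaminant")
}

RATIO_COL_RE <- "^Ratio (H/L|M/L|H/M) Exp([1-4])( R([0-9]+))?$"

new_site_table <- function(df, design, source = NA_character_,
                           n_replicates = NA_integer_,
                           filter_log = character(0)) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$site_id)) {
    stop("site ids must be unique", call. = FALSE)
  }
  structure(df, design = design, source = source,
            n_replicates = n_replicates, filter_log = filter_log,
            class = c("site_table", "data.frame"))
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites, %d ratio columns (source: %s)\n",
              nrow(x), length(ratio_columns(x)), attr(x, "source")))
  fl <- attr(x, "filter_log")
  if (length(fl)) cat(paste0("  ", fl, collapse = "\n"), "\n")
  invisible(x)
}

#' Ratio columns of a site table
#' @param table A `site_table`.
#' @return Character vector of ratio column names.
#' @export
ratio_columns <- function(table) {
  grep(RATIO_COL_RE, names(table), value = TRUE)
}

#' Read a phosphosite quantitation table
#'
#' Reads the tab-separated site-table dialect (one row per phosphosite;
#' reverse/contaminant flags encoded as `"+"`; ratio columns named
#' `"Ratio <pair> Exp<n> R<r>"`). Unparseable or non-positive ratio cells are
#' recorded as absent; rows with malformed metadata are kept and listed in the
#' `error_report` attribute rather than dropped.
#'
#' @param path Path to the TSV file.
#' @param design Experiment design attached to the table.
#' @param column_map Field-to-header map, see [default_column_map()].
#' @return A `site_table`.
#' @export
read_site_table <- function(path, design = default_experiment_design(),
                            column_map = default_column_map()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_design(design)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) stop(sprintf("empty site table: %s", path), call. = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  df <- data.frame(
    site_id = raw[[column_map["site_id"]]],
    protein = raw[[column_map["protein"]]],
    gene = raw[[column_map["gene"]]],
    position = suppressWarnings(as.integer(raw[[column_map["position"]]])),
    residue = raw[[column_map["residue"]]],
    window = raw[[column_map["window"]]],
    localization_prob = suppressWarnings(
      as.numeric(raw[[column_map["localization_prob"]]])),
    is_reverse = raw[[column_map["is_reverse"]]] == "+",
    is_contaminant = raw[[column_map["is_contaminant"]]] == "+",
    stringsAsFactors = FALSE
  )

  report <- character(0)
  note <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      ids <- df$site_id[which(idx)]
      report <<- c(report, sprintf("%s: %s", what, paste(ids, collapse = ", ")))
    }
  }
  note(is.na(df$position) | df$position < 1, "invalid position")
  note(nchar(df$window) != 31, "window not 31 residues")
  note(!substr(df$window, 16, 16) %in% c("S", "T", "Y"),
       "window centre not S/T/Y")
  note(is.na(df$localization_prob) | df$localization_prob < 0 |
         df$localization_prob > 1, "localization probability outside [0,1]")

  for (col in grep(RATIO_COL_RE, names(raw), value = TRUE)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.finite(v) & v <= 0
    if (any(bad)) {
      note(bad, sprintf("non-positive ratio in '%s'", col))
      v[bad] <- NA_real_
    }
    v[!is.finite(v)] <- NA_real_
    df[[col]] <- v
  }

  reps <- as.integer(sub(RATIO_COL_RE, "\\4",
                         grep(" R[0-9]+$", ratio_columns(df), value = TRUE)))
  tab <- new_site_table(df, design, source = path,
                        n_replicates = if (length(reps)) max(reps) else NA_integer_)
  attr(tab, "error_report") <- report
  tab
}

#' Write a site table in the TSV dialect read by [read_site_table()]
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every value bit-exactly.
#'
#' @param table A `site_table`.
#' @param path Output path.
#' @param column_map Field-to-header map.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path, column_map = default_column_map()) {
  out <- as.data.frame(table)
  out$is_reverse <- ifelse(out$is_reverse, "+", "")
  out$is_contaminant <- ifelse(out$is_contaminant, "+", "")
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    }
  }
  idx <- match(names(default_column_map()), names(out))
  names(out)[idx] <- unname(column_map[names(default_column_map())])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the ground-truth sidecar of a simulated phosphoproteome
#' @param truth Truth data frame from [simulate_phosphoproteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove decoy and contaminant entries
#'
#' Drops every site flagged as a reversed (decoy) database hit or a common
#' contaminant, logging the removal counts in the table's filter log.
#'
#' @param table A `site_table`.
#' @return The filtered `site_table`.
#' @export
filter_decoys_contaminants <- function(table) {
  drop <- table$is_reverse | table$is_contaminant
  msg <- sprintf("removed %d reverse and %d contaminant entries (%d rows dropped)",
                 sum(table$is_reverse), sum(table$is_contaminant), sum(drop))
  out <- table[!drop, , drop = FALSE]
  new_site_table(as.data.frame(out), attr(table, "design"),
                 source = attr(table, "source"),
                 n_replicates = attr(table, "n_replicates"),
                 filter_log = c(attr(table, "filter_log"), msg))
}

#' Classify phosphosites by localization probability
#'
#' Class I sites have localization probability >= 0.75, class II >= 0.5 and
#' class III below that; boundary values go to the higher class.
#'
#' @param p Numeric vector of localization probabilities in \[0, 1\].
#' @return Factor with levels `I`, `II`, `III`.
#' @export
#' @examples
#' classify_localization(c(1, 0.75, 0.5, 0.49))
classify_localization <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("localization probabilities must lie in [0, 1]", call. = FALSE)
  }
  cls <- cut(p, breaks = c(-Inf, 0.5, 0.75, Inf), labels = c("III", "II", "I"),
             right = FALSE)
  factor(cls, levels = c("I", "II", "III"))
}

#' Collapse replicate ratios and compute replicate QC
#'
#' For every site and (experiment, channel pair), replicate ratios are merged
#' as the median of the available log2 ratios, back-transformed. At least
#' `min_ratio_count` quantified replicates are required for the merged value
#' to be non-missing. The QC report gives the Pearson correlation of log2
#' ratios between each replicate pair, computed over sites quantified in both.
#'
#' @param tables A `site_table` with replicate-level ratio columns, or a list
#'   of single-replicate `site_table`s sharing the same design and site ids.
#' @param min_ratio_count Minimum quantified replicates per merged value.
#' @return A list with `table` (merged `site_table`, ratio columns without the
#'   replicate suffix) and `qc` (data frame: experiment, pair, rep_a, rep_b,
#'   n, pearson_r).
#' @export
merge_replicates <- function(tables, min_ratio_count = 1) {
  if (is.data.frame(tables)) {
    table <- tables
  } else {
    stopifnot(is.list(tables), length(tables) >= 1)
    designs <- lapply(tables, attr, "design")
    for (d in designs[-1]) {
      if (!identical(d, designs[[1]])) {
        stop("replicate tables must share the same experiment design",
             call. = FALSE)
      }
    }
    table <- tables[[1]]
    base_cols <- setdiff(names(table), ratio_columns(table))
    merged_df <- as.data.frame(table)[base_cols]
    for (i in seq_along(tables)) {
      ti <- as.data.frame(tables[[i]])
      if (!identical(ti$site_id, merged_df$site_id)) {
        stop("replicate tables must contain the same sites in the same order",
             call. = FALSE)
      }
      for (col in ratio_columns(tables[[i]])) {
        stripped <- sub(" R[0-9]+$", "", col)
        merged_df[[paste0(stripped, " R", i)]] <- ti[[col]]
      }
    }
    table <- new_site_table(merged_df, designs[[1]],
                            source = attr(tables[[1]], "source"),
                            n_replicates = length(tables))
  }

  rc <- ratio_columns(table)
  out <- as.data.frame(table)[setdiff(names(table), rc)]
  qc <- data.frame(experiment = integer(0), pair = character(0),
                   rep_a = integer(0), rep_b = integer(0), n = integer(0),
                   pearson_r = numeric(0), stringsAsFactors = FALSE)
  for (e in 1:4) {
    for (pair in RATIO_PAIRS) {
      cols <- grep(sprintf("^Ratio %s Exp%d R[0-9]+$", pair, e), names(table),
                   value = TRUE)
      if (!length(cols)) next
      reps <- sort(as.integer(sub("^.* R", "", cols)))
      cols <- cols[order(as.integer(sub("^.* R", "", cols)))]
      l2 <- log2(as.matrix(as.data.frame(table)[cols]))
      n_obs <- rowSums(is.finite(l2))
      med <- apply(l2, 1, stats::median, na.rm = TRUE)
      med[n_obs < min_ratio_count | n_obs == 0] <- NA_real_
      out[[ratio_column(e, pair)]] <- 2^med
      if (length(cols) >= 2) {
        for (a in seq_len(length(cols) - 1)) {
          for (b in seq(a + 1, length(cols))) {
            both <- is.finite(l2[, a]) & is.finite(l2[, b])
            r <- if (sum(both) >= 3) {
              stats::cor(l2[both, a], l2[both, b])
            } else NA_real_
            qc <- rbind(qc, data.frame(experiment = e, pair = pair,
                                       rep_a = reps[a], rep_b = reps[b],
                                       n = sum(both), pearson_r = r,
                                       stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  list(table = new_site_table(out, attr(table, "design"),
                              source = attr(table, "source"),
                              n_replicates = 1L,
                              filter_log = attr(table, "filter_log")),
       qc = qc)
}
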