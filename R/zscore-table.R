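# Reading, validating and summarising kinase-pair z-score tables.
#
# A z-score table holds, for each unordered pair of distinct kinases, one
# real-valued enrichment z-score per treatment (kinase substrate enrichment
# z-scores in the source data). Missing cells mean "no measured interaction
# for that treatment" and are never imputed as zero.

#' Construct a kinase-pair z-score table
#'
#' Validates and canonicalises a data frame of unordered kinase pairs with
#' one numeric z-score column per treatment. Pairs are stored with the two
#' kinase names in lexicographic order, so row order and within-pair order of
#' the input are irrelevant.
#'
#' @param df A data frame containing the two pair columns and at least one
#'   treatment column.
#' @param pair_columns Character vector of length 2 naming the columns that
#'   hold the two kinase names of each pair.
#' @param treatment_columns Character vector naming the z-score columns; by
#'   default every column other than the pair columns.
#'
#' @return An object of class `zscore_table`: a data frame with columns
#'   `kinase_a`, `kinase_b` (lexicographically ordered within each row)
#'   followed by one numeric column per treatment. `NA` entries are missing
#'   measurements.
#'
#' @examples
#' zscore_table(data.frame(kinase_a = c("K1", "K1", "K2"),
#'                         kinase_b = c("K2", "K3", "K3"),
#'                         trt = c(-2, 1.5, -0.5)))
#' @export
zscore_table <- function(df, pair_columns = c("kinase_a", "kinase_b"),
                         treatment_columns = setdiff(names(df), pair_columns)) {
  if (!is.data.frame(df)) {
    kc_abort("`df` must be a data frame", "kc_validation_error")
  }
  if (length(pair_columns) != 2L || !all(pair_columns %in% names(df))) {
    kc_abort(sprintf("pair columns %s not found in input",
                     paste(setdiff(pair_columns, names(df)), collapse = ", ")),
             "kc_format_error")
  }
  if (length(treatment_columns) < 1L) {
    kc_abort("at least one treatment column is required", "kc_format_error")
  }
  if (anyDuplicated(treatment_columns)) {
    kc_abort("treatment names must be unique", "kc_validation_error")
  }
  missing_trt <- setdiff(treatment_columns, names(df))
  if (length(missing_trt)) {
    kc_abort(sprintf("treatment columns not found: %s",
                     paste(missing_trt, collapse = ", ")),
             "kc_format_error")
  }

  a <- as.character(df[[pair_columns[1L]]])
  b <- as.character(df[[pair_columns[2L]]])
  bad_name <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad_name)) {
    kc_abort(sprintf("row %d: empty or missing kinase name", bad_name[1L]),
             "kc_format_error")
  }
  self <- which(a == b)
  if (length(self)) {
    kc_abort(sprintf("row %d: pair with identical kinase names ('%s')",
                     self[1L], a[self[1L]]),
             "kc_validation_error")
  }

  z <- lapply(treatment_columns, function(trt) {
    col <- df[[trt]]
    if (is.numeric(col)) return(as.numeric(col))
    raw <- trimws(as.character(col))
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(parsed) & !is.na(raw) & raw != "")
    if (length(bad)) {
      kc_abort(sprintf("row %d: cannot parse z-score '%s' in treatment '%s'",
                       bad[1L], raw[bad[1L]], trt),
               "kc_format_error")
    }
    parsed
  })
  names(z) <- treatment_columns

  # unordered-pair canonicalisation
  ka <- pmin(a, b)
  kb <- pmax(a, b)
  key <- paste(ka, kb, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    kc_abort(sprintf("row %d: duplicate unordered pair (%s, %s)",
                     dup[1L], ka[dup[1L]], kb[dup[1L]]),
             "kc_validation_error")
  }

  out <- data.frame(kinase_a = ka, kinase_b = kb, z,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("zscore_table", "data.frame")
  out
}

#' List the treatments of a z-score table
#' @param table A [zscore_table()].
#' @return Character vector of treatment names.
#' @export
treatments <- function(table) {
  stopifnot(inherits(table, "zscore_table"))
  setdiff(names(table), c("kinase_a", "kinase_b"))
}

#' List the kinases of a z-score table
#' @param table A [zscore_table()].
#' @return Sorted character vector of distinct kinase names.
#' @export
kinases <- function(table) {
  stopifnot(inherits(table, "zscore_table"))
  sort(unique(c(table$kinase_a, table$kinase_b)))
}

#' @export
print.zscore_table <- function(x, ...) {
  cat(sprintf("<zscore_table> %d kinase pairs, %d kinases, %d treatment(s): %s\n",
              nrow(x), length(kinases(x)), length(treatments(x)),
              paste(treatments(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

infer_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", tab = "\t", ",")
}

#' Read a kinase-pair z-score table from CSV/TSV
#'
#' The file must have a header row, two columns of kinase names and one
#' numeric column per treatment. The delimiter is inferred from the file
#' extension (`.csv` comma, `.tsv`/`.txt` tab) unless given explicitly.
#' Empty cells are recorded as missing, never as zero.
#'
#' @param path Path to the file.
#' @param pair_columns Names of the two kinase-name columns.
#' @param treatment_columns Names of the z-score columns; default all others.
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @return A [zscore_table()].
#' @export
load_zscore_table <- function(path, pair_columns = c("kinase_a", "kinase_b"),
                              treatment_columns = NULL, delim = NULL) {
  if (!file.exists(path)) {
    kc_abort(sprintf("file not found: %s", path), "kc_format_error")
  }
  delim <- delim %||% infer_delim(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                      na.strings = c("", "NA"), check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) {
      kc_abort(sprintf("malformed file %s: %s", path, conditionMessage(e)),
               "kc_format_error")
    })
  if (is.null(treatment_columns)) {
    treatment_columns <- setdiff(names(df), pair_columns)
  }
  zscore_table(df, pair_columns, treatment_columns)
}

#' Write a z-score table to CSV/TSV
#'
#' Inverse of [load_zscore_table()]: `load(write(x))` reproduces `x` up to
#' row order.
#'
#' @param table A [zscore_table()].
#' @param path Output path; delimiter inferred from the extension unless
#'   `delim` is given.
#' @param delim Field delimiter; `NULL` to infer.
#' @export
write_zscore_table <- function(table, path, delim = NULL) {
  stopifnot(inherits(table, "zscore_table"))
  delim <- delim %||% infer_delim(path)
  utils::write.table(as.data.frame(table), path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Merge kinase aliases in a z-score table
#'
#' Renames kinases according to `alias_map` and collapses the table onto the
#' merged names. This mirrors treating AKT isoforms 1 and 2 as a single
#' kinase when both carry identical z-scores. Pairs whose two members
#' collapse to the same merged name are removed; pairs that become duplicates
#' are deduplicated provided their z-scores agree per treatment within `tol`
#' (missing must match missing).
#'
#' @param table A [zscore_table()].
#' @param alias_map Named character vector, `old name -> merged name`.
#' @param tol Absolute tolerance for "same z-scores" among collapsing
#'   duplicates.
#' @return A [zscore_table()] over the merged kinase names. Idempotent:
#'   applying the same map twice equals applying it once.
#' @export
merge_aliases <- function(table, alias_map, tol = 1e-9) {
  stopifnot(inherits(table, "zscore_table"))
  if (length(alias_map) == 0L) return(table)
  if (is.null(names(alias_map))) {
    kc_abort("`alias_map` must be a named character vector", "kc_validation_error")
  }
  trts <- treatments(table)
  rename <- function(x) {
    hit <- match(x, names(alias_map))
    ifelse(is.na(hit), x, unname(alias_map[hit]))
  }
  a <- rename(table$kinase_a)
  b <- rename(table$kinase_b)
  keep <- a != b            # self-pairs created by the merge are dropped
  a <- a[keep]; b <- b[keep]
  z <- as.data.frame(table)[keep, trts, drop = FALSE]
  ka <- pmin(a, b); kb <- pmax(a, b)
  key <- paste(ka, kb, sep = "\r")

  first <- !duplicated(key)
  if (any(!first)) {
    ref <- match(key, key)  # index of first occurrence
    for (i in which(!first)) {
      j <- ref[i]
      for (trt in trts) {
        zi <- z[i, trt]; zj <- z[j, trt]
        same <- (is.na(zi) && is.na(zj)) ||
          (!is.na(zi) && !is.na(zj) && abs(zi - zj) <= tol)
        if (!same) {
          kc_abort(sprintf(
            "alias merge conflict for pair (%s, %s), treatment '%s': z-scores %s vs %s",
            ka[i], kb[i], trt, format(zj), format(zi)),
            "kc_conflict_error")
        }
      }
    }
  }
  out <- data.frame(kinase_a = ka[first], kinase_b = kb[first],
                    z[first, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  zscore_table(out, treatment_columns = trts)
}

#' Summary statistics of one sign of a treatment's z-scores
#'
#' Computes the summary reported for empirical kinase networks: count of
#' distinct kinases participating in retained interactions, and min, max,
#' mean and standard deviation of the strictly negative (or strictly
#' positive) z-scores of one treatment. Zeros and missing values are always
#' excluded.
#'
#' @param table A [zscore_table()].
#' @param treatment Treatment name.
#' @param sign `"negative"` or `"positive"`: which tail to retain.
#' @return An object of class `zscore_summary`: a list with fields
#'   `treatment`, `sign`, `n_kinases`, `n_values`, `min`, `max`, `mean`,
#'   `sd` (sample, n-1 denominator), `sd_pop` (population, n denominator)
#'   and `empty`. With no retained values the statistics are `NA` and
#'   `empty` is `TRUE`.
#'
#' @details The source data's summary table does not state whether its
#'   standard deviation uses the sample or population convention; both are
#'   reported here, with the sample convention in the `sd` field.
#' @export
summarise_zscores <- function(table, treatment,
                              sign = c("negative", "positive")) {
  stopifnot(inherits(table, "zscore_table"))
  sign <- match.arg(sign)
  if (!treatment %in% treatments(table)) {
    kc_abort(sprintf("treatment '%s' not present (have: %s)", treatment,
                     paste(treatments(table), collapse = ", ")),
             "kc_lookup_error")
  }
  z <- table[[treatment]]
  keep <- !is.na(z) & if (sign == "negative") z < 0 else z > 0
  zr <- z[keep]
  n <- length(zr)
  ks <- sort(unique(c(table$kinase_a[keep], table$kinase_b[keep])))
  out <- list(
    treatment = treatment, sign = sign,
    n_kinases = length(ks), n_values = n,
    min = if (n) min(zr) else NA_real_,
    max = if (n) max(zr) else NA_real_,
    mean = if (n) mean(zr) else NA_real_,
    sd = if (n > 1L) stats::sd(zr) else if (n == 1L) 0 else NA_real_,
    sd_pop = if (n) sqrt(mean((zr - mean(zr))^2)) else NA_real_,
    empty = n == 0L)
  class(out) <- "zscore_summary"
  out
}

#' @export
print.zscore_summary <- function(x, ...) {
  cat(sprintf("<zscore_summary> treatment %s, %s tail\n", x$treatment, x$sign))
  if (x$empty) {
    cat("  no retained z-scores\n")
  } else {
    cat(sprintf("  kinases %d  values %d  min %.4g  max %.4g  mean %.4g  sd %.4g (pop %.4g)\n",
                x$n_kinases, x$n_values, x$min, x$max, x$mean, x$sd, x$sd_pop))
  }
  invisible(x)
}
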