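#' @importFrom utils read.csv write.csv
NULL

#' Read a cross-set table from CSV
#'
#' Expects a header row and columns `cross_id`, `mean`, `seg_var`
#' (optionally `parent1`, `parent2`), decimal points, UTF-8. Row order is
#' preserved: the allocator breaks ties by input order.
#'
#' @param path Path to the CSV file.
#' @return A [cross_set()].
#' @examples
#' path <- system.file("extdata", "barley_crosses.csv",
#'                     package = "crossalloc")
#' read_cross_set(path)
#' @export
read_cross_set <- function(path) {
  if (!file.exists(path))
    ca_stop_validation("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) ca_stop_validation(
                   "cannot parse '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0)
    ca_stop_validation("'", path, "' contains no crosses")
  required <- c("cross_id", "mean", "seg_var")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    ca_stop_validation("'", path, "' is missing required column(s): ",
                       paste(missing, collapse = ", "))
  if (anyDuplicated(df$cross_id)) {
    dup <- df$cross_id[duplicated(df$cross_id)][1]
    ca_stop_validation("duplicate cross_id '", dup, "' in '", path, "'")
  }
  if (!is.numeric(df$mean) || any(!is.finite(df$mean))) {
    row <- which(!is.finite(suppressWarnings(as.numeric(df$mean))))[1]
    ca_stop_validation("non-numeric 'mean' in row ", row, " of '", path, "'")
  }
  if (!is.numeric(df$seg_var) || any(!is.finite(df$seg_var)) ||
      any(df$seg_var <= 0)) {
    row <- which(!is.finite(suppressWarnings(as.numeric(df$seg_var))) |
                   suppressWarnings(as.numeric(df$seg_var)) <= 0)[1]
    ca_stop_validation("field 'seg_var' must be a positive number; ",
                       "offending row ", row, " of '", path, "'")
  }
  cross_set(mu = df$mean, seg_var = df$seg_var, id = df$cross_id,
            parent1 = df$parent1, parent2 = df$parent2)
}

#' Write a cross set to CSV
#'
#' Inverse of [read_cross_set()]: columns `cross_id`, `parent1`, `parent2`,
#' `mean`, `seg_var`. Round-trips losslessly.
#'
#' @param cross_set A [cross_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cross_set <- function(cross_set, path) {
  cs <- as_cross_set(cross_set)
  out <- data.frame(cross_id = cs$id, parent1 = cs$parent1,
                    parent2 = cs$parent2, mean = cs$mu, seg_var = cs$seg_var,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 20-cross barley example data
#'
#' Predicted cross means and segregation variances for yield (dt/ha) of 20
#' doubled-haploid families from crosses of five registered six-row barley
#' varieties (ETI, JEN, MER, OTT, QUA) with four resistance donor lines
#' (146, ANT, D33, D37), estimated from parental marker data in a
#' resistance breeding experiment and treated here as known true values.
#' The set mixes elite x elite and donor x elite crosses: the variance of
#' the segregation standard deviations is about 0.05 times the variance of
#' the cross means.
#'
#' @return A [cross_set()] with 20 crosses.
#' @examples
#' b <- barley_crosses()
#' mean(b$mu)  # 88.6145
#' @export
barley_crosses <- function() {
  read_cross_set(system.file("extdata", "barley_crosses.csv",
                             package = "crossalloc", mustWork = TRUE))
}
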