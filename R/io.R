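#' Read an MID table from CSV
#'
#' Expected columns: `sample_id,fragment_name,m0,m1,...,mK`. Rows may be
#' ragged (fragments differ in carbon count): trailing cells of shorter
#' fragments are empty/NA. Each row's MID is returned dense and validated.
#'
#' @param path CSV file path.
#' @param normalize Renormalize each row to sum to 1 (default `TRUE`;
#'   raw intensity vectors are accepted that way).
#' @return A data frame `sample_id`, `fragment_name`, plus `m*` columns.
#' @export
read_mid_table <- function(path, normalize = TRUE) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("sample_id", "fragment_name")
  if (!all(need %in% names(df))) {
    stop("MID table ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (!length(mcols)) stop("MID table ", path, " has no m0..mK columns",
                           call. = FALSE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  for (i in seq_len(nrow(df))) {
    v <- as.numeric(df[i, mcols])
    v <- v[seq_len(max(which(!is.na(v))))]
    if (anyNA(v) || any(v < 0)) {
      stop("malformed MID in ", path, ": row ", i, " (sample '",
           df$sample_id[i], "', fragment '", df$fragment_name[i],
           "') has negative or internally missing intensities",
           call. = FALSE)
    }
    if (normalize) {
      if (sum(v) <= 0) stop("malformed MID in ", path, ": row ", i,
                            " sums to zero", call. = FALSE)
      v <- v / sum(v)
    }
    df[i, mcols] <- c(v, rep(NA_real_, length(mcols) - length(v)))
  }
  df[c(need, mcols)]
}

#' Extract one row of an MID table as a dense vector
#'
#' @param mid_table Result of [read_mid_table()] (or the `mids` element of
#'   [simulate_experiment()]).
#' @param row Row index.
#' @return Numeric MID without trailing NAs.
#' @export
mid_table_row <- function(mid_table, row) {
  mcols <- grep("^m[0-9]+$", names(mid_table), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  v <- as.numeric(mid_table[row, mcols])
  v[seq_len(max(which(!is.na(v))))]
}

#' Write an MID table to CSV
#'
#' @param mid_table Data frame as produced by [simulate_experiment()].
#' @param path Output CSV path.
#' @export
write_mid_table <- function(mid_table, path) {
  utils::write.csv(mid_table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Deconvolve every row of an MID table
#'
#' Applies [deconvolve_mid()] per sample x fragment and returns a tidy
#' results table, one row each.
#'
#' @param mid_table Data frame from [read_mid_table()].
#' @param fragments Named list of [fragment_spec()]s covering every
#'   `fragment_name` in the table.
#' @inheritParams deconvolve_mid
#' @return A data frame with the deconvolution summary per row (see
#'   [as.data.frame.deconvolution()]) plus `sample_id`.
#' @export
deconvolve_mid_table <- function(mid_table, fragments,
                                 method = c("strip", "fit"),
                                 p_nat = natural_13c_abundance(),
                                 threshold = 0.5, tol = 1e-9) {
  method <- match.arg(method)
  missing_frag <- setdiff(unique(mid_table$fragment_name), names(fragments))
  if (length(missing_frag)) {
    stop("no fragment_spec for: ", paste(missing_frag, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(mid_table)), function(i) {
    frag <- fragments[[mid_table$fragment_name[i]]]
    dec <- deconvolve_mid(mid_table_row(mid_table, i), frag,
                          method = method, p_nat = p_nat,
                          threshold = threshold, tol = tol)
    cbind(data.frame(sample_id = mid_table$sample_id[i],
                     stringsAsFactors = FALSE),
          as.data.frame(dec))
  })
  do.call(rbind, out)
}

#' Read pool and measurement tables
#'
#' Pool CSV columns: `name,content_nmol_per_mg_chl,carbon_number,c2_units`
#' (blank where inapplicable). Measurement CSV columns:
#' `pool,labeled_fraction_pct,incorporation_pmol,label_time_h` (subset as
#' applicable).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_pool_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "content_nmol_per_mg_chl") %in% names(df))) {
    stop("pool table ", path,
         " needs columns name, content_nmol_per_mg_chl", call. = FALSE)
  }
  df
}

#' @rdname read_pool_table
#' @export
read_measurement_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"pool" %in% names(df)) {
    stop("measurement table ", path, " needs a 'pool' column",
         call. = FALSE)
  }
  df
}

#' Write a derived-rate table to CSV
#'
#' @param rate_table Result of [build_rate_table()].
#' @param path Output CSV path.
#' @export
write_rate_table <- function(rate_table, path) {
  utils::write.csv(rate_table, path, row.names = FALSE, na = "")
  invisible(path)
}
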