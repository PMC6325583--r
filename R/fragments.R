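#' Define a measured analyte fragment
#'
#' A fragment is the carbon skeleton actually seen by GC-MS: the analyte
#' backbone (e.g. a 16-carbon palmitate chain, a 6-carbon galactose) plus any
#' carbons added by derivatization (the FAME methyl, TMS groups), which are
#' always at natural isotopic abundance. Only a subset of backbone positions
#' is reachable by the tracer: all of them for bicarbonate labeling, the
#' even-numbered acyl carbons only for [2-13C]acetate (one per C2 unit).
#'
#' @param name Identifier, e.g. `"16:0"` or `"galactose"`.
#' @param n_analyte_carbons Number of backbone carbons (>= 0).
#' @param n_labelable Number of tracer-reachable positions,
#'   `0 <= n_labelable <= n_analyte_carbons`.
#' @param n_derivatization_carbons Carbons added by derivatization, at
#'   natural abundance (default 0, i.e. a backbone-only analysis).
#' @return An object of class `fragment_spec`.
#' @examples
#' fragment_spec("16:0", 16, 8)            # acetate labeling, even carbons
#' fragment_spec("galactose", 6, 6)        # bicarbonate labeling
#' @export
fragment_spec <- function(name, n_analyte_carbons, n_labelable,
                          n_derivatization_carbons = 0L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_analyte_carbons <- check_count(n_analyte_carbons, "n_analyte_carbons")
  n_labelable <- check_count(n_labelable, "n_labelable")
  n_derivatization_carbons <- check_count(n_derivatization_carbons,
                                          "n_derivatization_carbons")
  if (n_labelable > n_analyte_carbons) {
    stop("'n_labelable' (", n_labelable, ") exceeds 'n_analyte_carbons' (",
         n_analyte_carbons, ") for fragment '", name, "'", call. = FALSE)
  }
  structure(
    list(name = name,
         n_analyte_carbons = n_analyte_carbons,
         n_labelable = n_labelable,
         n_derivatization_carbons = n_derivatization_carbons),
    class = "fragment_spec"
  )
}

check_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x)) {
    stop("'", what, "' must be a single non-negative integer", call. = FALSE)
  }
  as.integer(x)
}

#' Total carbons of a fragment (backbone + derivatization)
#' @param fragment A [fragment_spec()].
#' @return Integer carbon count.
#' @export
fragment_carbons <- function(fragment) {
  stopifnot(inherits(fragment, "fragment_spec"))
  fragment$n_analyte_carbons + fragment$n_derivatization_carbons
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s: %d backbone C (%d labelable), %d derivatization C\n",
              x$name, x$n_analyte_carbons, x$n_labelable,
              x$n_derivatization_carbons))
  invisible(x)
}

#' Built-in fragment definitions
#'
#' The fragments measured in the labeling experiments: galactose and glycerol
#' from the MGDG polar group (fully labelable with bicarbonate) and the common
#' saturated/unsaturated fatty acids (even-numbered acyl carbons labelable
#' with [2-13C]acetate, i.e. one position per C2 unit). Derivatization carbons
#' default to 0, i.e. the carbon-only backbone analysis; pass
#' `backbone_only = FALSE` to include the FAME methyl carbon (+1) and the TMS
#' carbons of per-silylated sugars/glycerol (+3 per hydroxyl).
#'
#' @param backbone_only Logical; if `TRUE` (default) derivatization carbons
#'   are 0 for every fragment.
#' @return A named list of [fragment_spec()] objects.
#' @export
default_fragments <- function(backbone_only = TRUE) {
  path <- system.file("extdata", "fragments.csv", package = "midtrace",
                      mustWork = TRUE)
  tab <- read_fragments(path)
  if (backbone_only) {
    tab <- lapply(tab, function(f) {
      f$n_derivatization_carbons <- 0L
      f
    })
  }
  tab
}

#' Read fragment definitions from CSV
#'
#' Expected columns: `name,n_analyte_carbons,n_labelable,n_derivatization_carbons`.
#'
#' @param path CSV file path.
#' @return Named list of [fragment_spec()] objects.
#' @export
read_fragments <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "n_analyte_carbons", "n_labelable",
            "n_derivatization_carbons")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("fragment file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    fragment_spec(df$name[i], df$n_analyte_carbons[i], df$n_labelable[i],
                  df$n_derivatization_carbons[i])
  })
  names(out) <- df$name
  out
}
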