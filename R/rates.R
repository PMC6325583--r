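#' Incorporation rate from a labeled fraction
#'
#' Amount of a pool replaced by newly synthesized material per unit time:
#' `content * labeled_fraction_pct / 100 / label_time`. With the standard
#' 1-h labeling this is the printed "incorporation rate" column.
#'
#' @param pool_content Pool size, nmol per mg chlorophyll.
#' @param labeled_fraction_pct Labeled fraction in percent, `[0, 100)`.
#' @param label_time Labeling duration in hours (default 1).
#' @return Incorporation rate, nmol per mg chlorophyll per hour.
#' @examples
#' incorporation_rate(400.92, 8.80)   # 35.28
#' @export
incorporation_rate <- function(pool_content, labeled_fraction_pct,
                               label_time = 1) {
  check_nonneg(pool_content, "pool_content")
  check_fraction_pct(labeled_fraction_pct)
  check_pos(label_time, "label_time")
  pool_content * labeled_fraction_pct / 100 / label_time
}

#' Turnover rate from a labeled fraction
#'
#' Under a steady-state pool with equal input and output fluxes, the
#' labeled fraction follows `f(t) = 1 - exp(-k t)`, so the rate constant is
#' `k = -log(1 - f) / t`. Estimated from the labeling (not decay) kinetics.
#'
#' @inheritParams incorporation_rate
#' @return Turnover rate k, per hour.
#' @examples
#' turnover_rate(8.80)    # 0.0921 -> prints as 0.092
#' @export
turnover_rate <- function(labeled_fraction_pct, label_time = 1) {
  check_fraction_pct(labeled_fraction_pct)
  check_pos(label_time, "label_time")
  -log(1 - labeled_fraction_pct / 100) / label_time
}

#' Carbon content of a lipid pool
#'
#' `carbon_number * content / 1000`, i.e. nmol lipid converted to umol of
#' carbon per mg chlorophyll.
#'
#' @param lipid_content nmol lipid per mg chlorophyll.
#' @param carbon_number Carbons per molecule (e.g. 43 for C18/C16 MGDG).
#' @return umol C per mg chlorophyll.
#' @examples
#' carbon_content(401, 43)   # 17.2
#' @export
carbon_content <- function(lipid_content, carbon_number) {
  check_nonneg(lipid_content, "lipid_content")
  check_nonneg(carbon_number, "carbon_number")
  carbon_number * lipid_content / 1000
}

#' Specific radioactivity of a lipid pool
#'
#' Proportion of labeled carbon, 14C/(14C + 12C), on the 1e-6 scale:
#' pmol 14C divided by umol total C.
#'
#' @param incorporation_pmol pmol 14C per mg chlorophyll per hour.
#' @param carbon_content umol C per mg chlorophyll (> 0).
#' @return Specific radioactivity, x 1e-6.
#' @examples
#' specific_radioactivity_lipid(3.58, 17.2)   # 0.208
#' @export
specific_radioactivity_lipid <- function(incorporation_pmol, carbon_content) {
  check_nonneg(incorporation_pmol, "incorporation_pmol")
  check_pos(carbon_content, "carbon_content")
  incorporation_pmol / carbon_content
}

#' Acetate-unit content of a fatty acid pool
#'
#' `content * c2_units`: nmol fatty acid converted to nmol of C2 (acetate)
#' units per mg chlorophyll. C2 units: 7 for 14:0, 8 for 16:0, 9 for 18:0.
#'
#' @param fa_content nmol fatty acid per mg chlorophyll.
#' @param c2_units Acetate units per molecule.
#' @return nmol C2 per mg chlorophyll.
#' @examples
#' c2_content(1078, 8)   # 8624
#' @export
c2_content <- function(fa_content, c2_units) {
  check_nonneg(fa_content, "fa_content")
  check_nonneg(c2_units, "c2_units")
  fa_content * c2_units
}

#' Specific radioactivity of a fatty acid pool
#'
#' `1000 * incorporation / c2_content`, on the 1e-6 scale (the factor 1000
#' converts pmol/nmol to the same labeled-carbon proportion as the lipid
#' variant).
#'
#' @param incorporation_pmol pmol 14C per mg chlorophyll per hour.
#' @param c2_content nmol C2 per mg chlorophyll (> 0).
#' @return Specific radioactivity, x 1e-6.
#' @examples
#' specific_radioactivity_fa(0.70, 43.3)   # 16.2
#' @export
specific_radioactivity_fa <- function(incorporation_pmol, c2_content) {
  check_nonneg(incorporation_pmol, "incorporation_pmol")
  check_pos(c2_content, "c2_content")
  1000 * incorporation_pmol / c2_content
}

#' Specific growth rate from a doubling time
#'
#' `log(2) / doubling_time`; 12 h doubling gives 0.058 per hour.
#'
#' @param doubling_time Hours (> 0).
#' @return Specific growth rate, per hour.
#' @export
growth_rate_from_doubling <- function(doubling_time) {
  check_pos(doubling_time, "doubling_time")
  log(2) / doubling_time
}

#' Degradation rate from turnover and growth
#'
#' At steady state, turnover = specific growth + degradation, so the
#' degradation rate is `turnover - growth`. In vitro (isolated plastids)
#' turnover can fall below the growth rate; the difference is then floored
#' at 0 and flagged rather than treated as an error.
#'
#' @param turnover Turnover rate, per hour (>= 0).
#' @param growth Specific growth rate, per hour (>= 0).
#' @return Numeric degradation rate with attribute `below_growth` (logical:
#'   was the raw difference negative and floored?).
#' @examples
#' degradation_rate(0.092, 0.058)   # 0.034
#' @export
degradation_rate <- function(turnover, growth) {
  check_nonneg(turnover, "turnover")
  check_nonneg(growth, "growth")
  raw <- turnover - growth
  out <- pmax(raw, 0)
  attr(out, "below_growth") <- raw < 0
  out
}

#' Convert a radioactivity count rate to an amount of substrate
#'
#' With substrate specific activity in mCi/mmol and 1 Ci = 2.22e12 dpm,
#' 1 mCi/mmol = 2.22 dpm/pmol, so `pmol = dpm / (2.22 * specific_activity)`.
#'
#' @param dpm Disintegrations per minute (> 0).
#' @param specific_activity Substrate specific activity, mCi per mmol
#'   (> 0); 58.8 for the carrier-diluted substrates used here.
#' @return Amount in pmol.
#' @examples
#' dpm_to_pmol(130.5, 58.8)   # ~1 pmol
#' @export
dpm_to_pmol <- function(dpm, specific_activity = 58.8) {
  check_pos(dpm, "dpm")
  check_pos(specific_activity, "specific_activity")
  dpm / (2.22 * specific_activity)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("'", what, "' must be non-negative", call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop("'", what, "' must be positive", call. = FALSE)
  }
  invisible(x)
}

check_fraction_pct <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x >= 100)) {
    stop("'labeled_fraction_pct' must lie in [0, 100): a pool cannot be ",
         "fully replaced in finite time under the steady-state model",
         call. = FALSE)
  }
  invisible(x)
}

#' Experiment-level constants
#'
#' @param p_nat Natural 13C abundance.
#' @param label_time Labeling duration, h.
#' @param doubling_time Culture doubling time, h; the specific growth rate
#'   is derived as `log(2)/doubling_time` unless given explicitly.
#' @param specific_growth_rate Per hour; must equal `log(2)/doubling_time`
#'   within 2% when both are supplied.
#' @param substrate_specific_activity mCi per mmol, for dpm conversions.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(p_nat = natural_13c_abundance(),
                              label_time = 1, doubling_time = 12,
                              specific_growth_rate = NULL,
                              substrate_specific_activity = 58.8) {
  check_pos(label_time, "label_time")
  check_pos(doubling_time, "doubling_time")
  mu <- growth_rate_from_doubling(doubling_time)
  if (!is.null(specific_growth_rate)) {
    check_pos(specific_growth_rate, "specific_growth_rate")
    if (abs(specific_growth_rate - mu) / mu > 0.02) {
      stop("specific_growth_rate (", specific_growth_rate,
           ") is inconsistent with doubling_time (", doubling_time,
           " h -> ", signif(mu, 3), " per h)", call. = FALSE)
    }
    mu <- specific_growth_rate
  }
  structure(
    list(p_nat = check_prob(p_nat, "p_nat", allow_one = FALSE),
         label_time = label_time,
         doubling_time = doubling_time,
         specific_growth_rate = mu,
         substrate_specific_activity = substrate_specific_activity),
    class = "experiment_config"
  )
}

#' Assemble a derived-rate table
#'
#' Applies the table-kind-specific formulas to a set of pools and
#' measurements and returns one row per measurement, with derived columns
#' both at full precision and rounded (half-to-even) to the precision the
#' corresponding published table prints.
#'
#' Kinds:
#' \describe{
#'   \item{`bicarbonate_lipid`}{lipid classes labeled with 14C-bicarbonate:
#'     carbon content (umol C/mg chl) and specific radioactivity (x 1e-6).}
#'   \item{`bicarbonate_mid`}{MGDG moieties labeled with 13C-bicarbonate:
#'     incorporation rate (nmol/mg chl/h) and turnover rate (per h) from
#'     the highly labeled fraction.}
#'   \item{`acetate_fa`}{fatty acids labeled with 2-14C-acetate: C2-unit
#'     content (nmol C2/mg chl) and specific radioactivity (x 1e-6).}
#'   \item{`acetate_mid`}{fatty acids labeled with 2-13C-acetate:
#'     incorporation and turnover rates from the labeled fraction.}
#' }
#'
#' @param pools Data frame with columns `name`,
#'   `content_nmol_per_mg_chl`, and `carbon_number` and/or `c2_units`
#'   (NA where inapplicable).
#' @param measurements Data frame with columns `pool` plus, depending on
#'   kind, `labeled_fraction_pct` and/or `incorporation_pmol`, and
#'   optionally `label_time_h`. `NA` fractions ("not detected") propagate
#'   as `NA` derived values.
#' @param config An [experiment_config()].
#' @param table_kind One of the four kinds above.
#' @return A `data.frame`, one row per measurement, with full-precision
#'   derived columns and `*_printed` twins rounded at the published
#'   precision.
#' @export
build_rate_table <- function(pools, measurements,
                             config = experiment_config(),
                             table_kind = c("bicarbonate_lipid",
                                            "bicarbonate_mid",
                                            "acetate_fa", "acetate_mid")) {
  table_kind <- match.arg(table_kind)
  stopifnot(is.data.frame(pools), is.data.frame(measurements),
            inherits(config, "experiment_config"))
  if (nrow(measurements) == 0L) {
    return(data.frame(pool = character(0)))
  }
  if (!all(c("name", "content_nmol_per_mg_chl") %in% names(pools))) {
    stop("'pools' needs columns name, content_nmol_per_mg_chl",
         call. = FALSE)
  }
  idx <- match(measurements$pool, pools$name)
  if (anyNA(idx)) {
    stop("measurement references unknown pool(s): ",
         paste(unique(measurements$pool[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  content <- pools$content_nmol_per_mg_chl[idx]
  lt <- if ("label_time_h" %in% names(measurements)) {
    ifelse(is.na(measurements$label_time_h), config$label_time,
           measurements$label_time_h)
  } else rep(config$label_time, nrow(measurements))

  need_col <- function(col) {
    if (!col %in% names(measurements)) {
      stop("table kind '", table_kind, "' needs measurement column '", col,
           "'", call. = FALSE)
    }
    measurements[[col]]
  }
  digits <- table_digits(table_kind)

  if (table_kind %in% c("bicarbonate_mid", "acetate_mid")) {
    frac <- need_col("labeled_fraction_pct")
    ok <- !is.na(frac)
    inc <- turn <- rep(NA_real_, length(frac))
    inc[ok] <- mapply(incorporation_rate, content[ok], frac[ok], lt[ok])
    turn[ok] <- mapply(turnover_rate, frac[ok], lt[ok])
    deg <- degradation_rate(ifelse(is.na(turn), 0, turn),
                            config$specific_growth_rate)
    out <- data.frame(
      pool = measurements$pool,
      content_nmol_per_mg_chl = content,
      labeled_fraction_pct = frac,
      incorporation_rate = inc,
      turnover_rate = turn,
      degradation_rate = ifelse(is.na(turn), NA_real_, as.numeric(deg)),
      below_growth = ifelse(is.na(turn), NA, attr(deg, "below_growth")),
      stringsAsFactors = FALSE
    )
    out$incorporation_rate_printed <- round(inc, digits["incorporation_rate"])
    out$turnover_rate_printed <- round(turn, digits["turnover_rate"])
  } else if (table_kind == "bicarbonate_lipid") {
    if (!"carbon_number" %in% names(pools) ||
        anyNA(pools$carbon_number[idx])) {
      stop("table kind 'bicarbonate_lipid' needs pool column ",
           "'carbon_number'", call. = FALSE)
    }
    inc_pmol <- need_col("incorporation_pmol")
    cc <- carbon_content(content, pools$carbon_number[idx])
    sr <- ifelse(is.na(inc_pmol), NA_real_,
                 inc_pmol / lt / cc)
    out <- data.frame(
      pool = measurements$pool,
      incorporation_pmol = inc_pmol,
      content_nmol_per_mg_chl = content,
      carbon_content = cc,
      specific_radioactivity = sr,
      stringsAsFactors = FALSE
    )
    out$carbon_content_printed <- signif_round(cc, 3)
    out$specific_radioactivity_printed <-
      round(sr, digits["specific_radioactivity"])
  } else { # acetate_fa
    if (!"c2_units" %in% names(pools) || anyNA(pools$c2_units[idx])) {
      stop("table kind 'acetate_fa' needs pool column 'c2_units'",
           call. = FALSE)
    }
    inc_pmol <- need_col("incorporation_pmol")
    c2 <- c2_content(content, pools$c2_units[idx])
    sr <- ifelse(is.na(inc_pmol), NA_real_,
                 1000 * inc_pmol / lt / c2)
    out <- data.frame(
      pool = measurements$pool,
      incorporation_pmol = inc_pmol,
      content_nmol_per_mg_chl = content,
      c2_content = c2,
      specific_radioactivity = sr,
      stringsAsFactors = FALSE
    )
    out$c2_content_printed <- signif_round(c2, 4)
    out$specific_radioactivity_printed <- signif_round(sr, 3)
  }
  out
}

# Printed decimal places per derived column, by table kind.
table_digits <- function(table_kind) {
  switch(table_kind,
    bicarbonate_mid = c(incorporation_rate = 2, turnover_rate = 3),
    acetate_mid = c(incorporation_rate = 2, turnover_rate = 3),
    bicarbonate_lipid = c(specific_radioactivity = 3),
    acetate_fa = c(specific_radioactivity = 3)
  )
}

# Round to significant digits with round-half-even on the last digit
# (base signif() rounds half away from zero in some representations;
# printed tables use 3-4 significant figures for contents).
signif_round <- function(x, digits) {
  out <- x
  ok <- !is.na(x) & x != 0
  mag <- floor(log10(abs(x[ok])))
  dec <- digits - 1 - mag
  out[ok] <- round(x[ok], dec)
  out
}
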