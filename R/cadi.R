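#' Yearly average of a dated series
#'
#' Arithmetic mean of the observations falling in a calendar year; missing
#' days are simply absent from the mean.
#'
#' @param values Numeric vector of nonnegative observations.
#' @param dates Dates (or coercible) parallel to `values`.
#' @param year Calendar year.
#' @param label Optional label (e.g. the word) used in error messages.
#' @return The mean over observed days within the year.
#' @export
yearly_average <- function(values, dates, year, label = NULL) {
  dates <- as.Date(dates)
  sel <- as.integer(format(dates, "%Y")) == as.integer(year)
  if (!any(sel)) {
    stop("no observations in year ", year,
         if (!is.null(label)) paste0(" for ", label) else "")
  }
  mean(values[sel])
}

#' Aggregate daily regional trends to region x word x year means
#'
#' @param trends Data frame (region, word, date, value).
#' @return Data frame (region, word, year, gamma).
#' @export
aggregate_regional_trends <- function(trends) {
  dt <- as.data.table(trends)
  dt[, yr := as.integer(format(as.Date(date), "%Y"))]
  out <- dt[, .(gamma = mean(value)), by = .(region, word, yr)]
  setnames(out, "yr", "year")
  setorder(out, region, word, year)
  as.data.frame(out)
}

#' Aggregate daily national trends to word x year means
#'
#' @param trends Data frame (word, date, value).
#' @return Data frame (word, year, beta).
#' @export
aggregate_national_trends <- function(trends) {
  dt <- as.data.table(trends)
  dt[, yr := as.integer(format(as.Date(date), "%Y"))]
  out <- dt[, .(beta = mean(value)), by = .(word, yr)]
  setnames(out, "yr", "year")
  setorder(out, word, year)
  as.data.frame(out)
}

#' Yearly word weights from relevance and national trend volume
#'
#' For each word i and year y, phi(i, y) = alpha(i) * beta(i, y) combines
#' the word's relevance to the targets with its national search volume;
#' the weight w(i, y) = phi(i, y) / sum_i phi(i, y) is the word's share of
#' total impact in that year, so weights sum to one within each year.
#'
#' @param pod Dictionary data frame with columns `word`, `alpha`.
#' @param national Data frame (word, year, beta), e.g. from
#'   [aggregate_national_trends()].
#' @return Data frame (word, year, phi, w).
#' @export
compute_weights <- function(pod, national) {
  if (nrow(pod) == 0L) stop("empty dictionary: no words to weight")
  if (any(pod$alpha < 0)) stop("'alpha' must be nonnegative")
  if (anyDuplicated(pod$word)) stop("duplicate words in dictionary")
  dt <- as.data.table(national)
  dt <- dt[word %in% pod$word]
  years <- sort(unique(dt$year))
  miss <- data.table::CJ(word = pod$word, year = years)[!dt, on = c("word", "year")]
  if (nrow(miss)) {
    stop("missing national trend for ",
         paste(sprintf("(%s, %d)", miss$word, miss$year), collapse = ", "))
  }
  if (any(dt$beta < 0)) stop("'beta' must be nonnegative")
  dt[, alpha := pod$alpha[match(word, pod$word)]]
  dt[, phi := alpha * beta]
  bad <- dt[, .(total = sum(phi)), by = year][total <= 0]
  if (nrow(bad)) {
    stop("sum of phi is zero in year(s) ",
         paste(bad$year, collapse = ", "),
         ": all words irrelevant or untrended that year")
  }
  dt[, w := phi / sum(phi), by = year]
  out <- dt[, c("word", "year", "phi", "w")]
  setorder(out, year, word)
  as.data.frame(out)
}

#' Population-adjust a regional trend panel
#'
#' gamma_bar(r, i, y) = gamma(r, i, y) / population(r, y): yearly search
#' intensity per person.
#'
#' @param panel Data frame (region, word, year, gamma).
#' @param pop Data frame (region, year, population), population > 0 persons.
#' @return The panel with a `gamma_bar` column added.
#' @export
population_adjust <- function(panel, pop) {
  dt <- as.data.table(panel)
  pp <- as.data.table(pop)
  if (any(pp$population <= 0)) {
    bad <- pp[population <= 0][1]
    stop("nonpositive population for (", bad$region, ", ", bad$year, ")")
  }
  merged <- merge(dt, pp, by = c("region", "year"), all.x = TRUE)
  if (anyNA(merged$population)) {
    bad <- unique(merged[is.na(population), c("region", "year")])[1]
    stop("missing population for (", bad$region, ", ", bad$year, ")")
  }
  merged[, gamma_bar := gamma / population]
  out <- merged[, c("region", "word", "year", "gamma", "gamma_bar")]
  setorder(out, region, word, year)
  as.data.frame(out)
}

#' Efficacy-coefficient score of one indicator value
#'
#' Linear rescaling of `value` within the \[lo, hi\] envelope onto
#' \[100 - tau, 100\]: `(value - lo) / (hi - lo) * tau + (100 - tau)`.
#' When the envelope is degenerate (hi == lo, the indicator conveys no
#' regional information) the normalized fraction is taken as 1/2, scoring
#' `100 - tau/2`.
#'
#' @param value Numeric vector of indicator values.
#' @param lo,hi Envelope bounds (vectors recycled against `value`).
#' @param tau Range parameter in (0, 100\]; default 40 scores onto
#'   \[60, 100\].
#' @return Numeric vector of scores in \[100 - tau, 100\].
#' @export
efficacy_score <- function(value, lo, hi, tau = 40) {
  if (tau <= 0 || tau > 100) stop("'tau' must lie in (0, 100]")
  n <- length(value)
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  eps <- 1e-9 * pmax(1, abs(hi - lo))
  if (any(value < lo - eps | value > hi + eps)) {
    stop("'value' outside [lo, hi]")
  }
  degenerate <- hi <= lo
  frac <- ifelse(degenerate, 0.5, (value - lo) / (hi - lo))
  frac <- pmin(1, pmax(0, frac))
  frac * tau + (100 - tau)
}

#' Compute the Composite Anxiety and Depression Index
#'
#' CADI(r, y) = sum_i score(gamma_bar(r, i, y); min_r, max_r, tau) * w(i, y),
#' where the min and max are taken over all regions within the same
#' (word, year) cell (including region r itself) and the scores follow
#' [efficacy_score()]. As a convex combination of per-word scores, every
#' CADI lies in \[100 - tau, 100\]; with the default tau = 40 the index runs
#' from 60 (a region at the cross-region minimum for every word) to 100 (at
#' the maximum for every word). Larger values indicate more severe negative
#' public mental health.
#'
#' @param panel Population-adjusted panel (region, word, year, gamma_bar),
#'   balanced: every (word, year) observed for every region of that year.
#' @param weights Data frame (word, year, w) as from [compute_weights()],
#'   covering every (word, year) of the panel.
#' @param tau Range parameter in (0, 100\]; default 40.
#' @return Data frame of class `cadi_table` (region, year, cadi,
#'   cadi_adjusted) with `cadi_adjusted` = NA until [penetration_adjust()]
#'   is applied; `tau` stored as an attribute.
#' @export
compute_cadi <- function(panel, weights, tau = 40) {
  if (tau <= 0 || tau > 100) stop("'tau' must lie in (0, 100]")
  if (!"gamma_bar" %in% names(panel)) {
    stop("panel has no 'gamma_bar' column; apply population_adjust() first")
  }
  dt <- as.data.table(panel)
  if (anyDuplicated(dt[, c("region", "word", "year")])) {
    stop("duplicate (region, word, year) rows in panel")
  }
  wt <- as.data.table(weights)
  miss_w <- unique(dt[, c("word", "year")])[!wt, on = c("word", "year")]
  if (nrow(miss_w)) {
    stop("weights missing for ",
         paste(sprintf("(%s, %d)", miss_w$word, miss_w$year), collapse = ", "))
  }
  # balance: every (word, year) present for every region observed that year
  counts <- dt[, .(n_obs = .N), by = .(word, year)]
  nregion <- dt[, .(n_obs = length(unique(region))), by = year]
  if (any(nregion$n_obs < 2L)) stop("need at least 2 regions per year")
  chk <- merge(counts, nregion, by = "year", suffixes = c("", "_regions"))
  bad <- chk[n_obs != n_obs_regions]
  if (nrow(bad)) {
    stop("unbalanced panel: (", bad$word[1], ", ", bad$year[1],
         ") missing for some region")
  }
  dt[, `:=`(lo = min(gamma_bar), hi = max(gamma_bar)), by = .(word, year)]
  dt[, score := efficacy_score(gamma_bar, lo, hi, tau)]
  dt <- merge(dt, wt[, c("word", "year", "w")], by = c("word", "year"))
  out <- dt[, .(cadi = sum(score * w)), by = .(region, year)]
  setorder(out, region, year)
  out <- as.data.frame(out)
  out$cadi_adjusted <- NA_real_
  attr(out, "tau") <- tau
  class(out) <- c("cadi_table", "data.frame")
  out
}

utils::globalVariables(c("n_obs_regions", "total"))

#' Penetration-adjust a CADI table
#'
#' Rescales each year's index by the year-over-year national Internet
#' penetration ratio, CADI~ = CADI * pi(y) / pi(y - 1), removing growth in
#' the online population from the vertical comparison. The first year of
#' the span has no preceding year; its ratio is taken as 1.
#'
#' @param table A `cadi_table` (or data frame with region, year, cadi).
#' @param pen Data frame (year, penetration), penetration > 0.
#' @return The table with `cadi_adjusted` filled in.
#' @export
penetration_adjust <- function(table, pen) {
  if (any(pen$penetration <= 0)) stop("penetration values must be > 0")
  if (anyDuplicated(pen$year)) stop("duplicate years in penetration series")
  years <- sort(unique(table$year))
  first <- years[1L]
  pi_of <- setNames(pen$penetration, pen$year)
  ratio <- vapply(years, function(y) {
    if (y == first) return(1)
    cur <- pi_of[as.character(y)]
    prev <- pi_of[as.character(y - 1L)]
    if (is.na(cur)) stop("penetration missing for year ", y)
    if (is.na(prev)) stop("penetration missing for year ", y - 1L,
                          " (needed to adjust year ", y, ")")
    unname(cur / prev)
  }, numeric(1))
  names(ratio) <- years
  table$cadi_adjusted <- table$cadi * ratio[as.character(table$year)]
  table
}

#' @export
print.cadi_table <- function(x, ...) {
  tau <- attr(x, "tau")
  cat("CADI table:", length(unique(x$region)), "regions x",
      length(unique(x$year)), "years",
      if (!is.null(tau)) sprintf("(tau = %g, range [%g, 100])", tau, 100 - tau),
      "\n")
  cat(sprintf("  cadi: min %.3f, median %.3f, max %.3f\n",
              min(x$cadi), median(x$cadi), max(x$cadi)))
  if (!all(is.na(x$cadi_adjusted))) {
    cat(sprintf("  cadi_adjusted: min %.3f, max %.3f\n",
                min(x$cadi_adjusted), max(x$cadi_adjusted)))
  }
  invisible(x)
}
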