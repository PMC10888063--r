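#' Weighted prevalence of mental disorders by region
#'
#' prevalence(r) = sum(weight * disorder) / sum(weight) over the records of
#' region r. Records with a missing disorder status are dropped (listwise
#' within region) before weighting; prevalence is invariant to rescaling a
#' region's weights by a positive constant.
#'
#' @param records Data frame (region, weight, disorder) with weight > 0 and
#'   disorder in \{0, 1\} (NA allowed, dropped).
#' @return Named numeric vector of prevalences in \[0, 1\], sorted by region.
#' @export
weighted_prevalence <- function(records) {
  stopifnot(all(c("region", "weight", "disorder") %in% names(records)))
  if (nrow(records) == 0L) return(setNames(numeric(), character()))
  records <- records[!is.na(records$disorder), , drop = FALSE]
  if (any(records$weight <= 0)) stop("sampling weights must be positive")
  if (!all(records$disorder %in% c(0, 1))) {
    stop("'disorder' must be a binary 0/1 indicator")
  }
  num <- tapply(records$weight * records$disorder, records$region, sum)
  den <- tapply(records$weight, records$region, sum)
  out <- num / den
  out[order(names(out))]
}

# all permutations of 1..n as an (n! x n) matrix, deterministic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    rest <- seq_len(n)[-k]
    out[r + seq_len(rows), 1L] <- k
    out[r + seq_len(rows), -1L] <- matrix(rest[sub], rows, n - 1L)
    r <- r + rows
  }
  out
}

kendall_tau_b <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  num <- sum(sx * sy) / 2
  n0 <- n * (n - 1) / 2
  t1 <- sum(choose(table(x), 2))
  t2 <- sum(choose(table(y), 2))
  den <- sqrt((n0 - t1) * (n0 - t2))
  if (den == 0) return(NA_real_)
  num / den
}

# two-sided permutation p-value for Pearson's r (exhaustive enumeration)
perm_p_pearson <- function(x, y) {
  n <- length(x)
  perms <- all_permutations(n)
  yp <- matrix(y[perms], nrow(perms), n)
  xc <- x - mean(x)
  stat <- abs(as.numeric(yp %*% xc))  # |cov| up to constants; sd(y) fixed
  obs <- abs(sum(xc * y))
  mean(stat >= obs - 1e-12)
}

perm_p_kendall <- function(x, y) {
  n <- length(x)
  perms <- all_permutations(n)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  obs <- abs(sum(sx * sy))
  cnt <- 0L
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    if (abs(sum(sx * sy[p, p])) >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

#' Pearson, Kendall and Spearman correlations with p-values
#'
#' Computes the Pearson product-moment coefficient, tie-corrected Kendall
#' tau-b, and the Spearman rank coefficient between two equal-length
#' vectors, with two-sided p-values. For small samples (n <= `exact_max_n`)
#' p-values are exact permutation probabilities over all n! orderings;
#' otherwise the usual asymptotic approximations are used. A zero-variance
#' input makes the coefficients undefined: they are reported as NA with a
#' warning, never as 0.
#'
#' @param x,y Numeric vectors of equal length >= 3. Pairs with missing
#'   values are deleted.
#' @param exact_max_n Largest n for which exact permutation p-values are
#'   enumerated (default 9).
#' @return Object of class `cadi_correlation`: list with `pearson`,
#'   `kendall`, `spearman`, `p_values` (named vector), `n`, `method`.
#' @export
correlation_suite <- function(x, y, exact_max_n = 9L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  pv <- c(pearson = NA_real_, kendall = NA_real_, spearman = NA_real_)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in 'x' or 'y': correlation undefined, reported as NA")
    est <- list(pearson = NA_real_, kendall = NA_real_, spearman = NA_real_)
    method <- "undefined"
  } else {
    est <- list(pearson = cor(x, y),
                kendall = cor(x, y, method = "kendall"),
                spearman = cor(x, y, method = "spearman"))
    if (n <= exact_max_n) {
      method <- "exact permutation"
      pv["pearson"] <- perm_p_pearson(x, y)
      pv["kendall"] <- perm_p_kendall(x, y)
      pv["spearman"] <- perm_p_pearson(rank(x), rank(y))
    } else {
      method <- "asymptotic"
      pv["pearson"] <- cor.test(x, y, method = "pearson")$p.value
      pv["kendall"] <- suppressWarnings(
        cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
      pv["spearman"] <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
    }
  }
  structure(list(pearson = est$pearson, kendall = est$kendall,
                 spearman = est$spearman, p_values = pv, n = n,
                 method = method),
            class = "cadi_correlation")
}

#' @export
print.cadi_correlation <- function(x, ...) {
  cat("Correlation report (n =", x$n, ", p-values:", x$method, ")\n")
  m <- data.frame(
    coefficient = c(x$pearson, x$kendall, x$spearman),
    p_value = unname(x$p_values),
    row.names = c("Pearson", "Kendall tau-b", "Spearman")
  )
  print(round(m, 4))
  invisible(x)
}

#' Validate a CADI table against survey prevalence
#'
#' Joins the weighted per-region prevalence of mental disorders from survey
#' microdata with the index of a chosen year and runs the correlation suite
#' on the paired regions.
#'
#' @param cadi_table Data frame (region, year, cadi, ...).
#' @param survey Data frame (region, weight, disorder).
#' @param year Calendar year of the index to validate.
#' @param use_adjusted Use the penetration-adjusted index if available.
#' @return List with `prevalence` (named vector), `cadi` (named vector),
#'   and `report` (a `cadi_correlation`).
#' @export
validate_cadi <- function(cadi_table, survey, year,
                          use_adjusted = FALSE) {
  prev <- weighted_prevalence(survey)
  sub <- cadi_table[cadi_table$year == year, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no CADI rows for year ", year)
  col <- if (use_adjusted && !all(is.na(sub$cadi_adjusted))) "cadi_adjusted" else "cadi"
  idx <- setNames(sub[[col]], sub$region)
  common <- intersect(names(prev), names(idx))
  if (length(common) < 3L) stop("fewer than 3 regions shared by survey and index")
  report <- correlation_suite(idx[common], prev[common])
  list(prevalence = prev[common], cadi = idx[common], report = report)
}
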