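#' Build the regression design matrix and response
#'
#' Columns: intercept, the eight covariates, and one indicator per calendar
#' year except the earliest (reference coding), named `year<YYYY>`. A
#' single-year panel is allowed and yields zero dummy columns. Collinear
#' (rank-deficient) designs are rejected with the offending columns named.
#'
#' @param panel Data frame with columns region, year, the eight covariates
#'   of [covariate_names()], and `cadi` (the response).
#' @return List with `X` (matrix), `y` (response), `years`, `n`.
#' @export
build_design <- function(panel) {
  need <- c("region", "year", covariate_names(), "cadi")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  modeled <- panel[, c(covariate_names(), "cadi")]
  if (anyNA(modeled)) {
    bad <- names(modeled)[vapply(modeled, anyNA, logical(1))]
    stop("missing values in modeled column(s): ", paste(bad, collapse = ", "))
  }
  years <- sort(unique(panel$year))
  X <- cbind(`(Intercept)` = 1, as.matrix(panel[, covariate_names()]))
  for (y in years[-1L]) {
    X <- cbind(X, as.integer(panel$year == y))
    colnames(X)[ncol(X)] <- paste0("year", y)
  }
  rownames(X) <- NULL
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("collinear design: column(s) ", paste(dep, collapse = ", "),
         " linearly dependent on the others")
  }
  list(X = X, y = panel$cadi, years = years, n = nrow(X))
}

new_regression_result <- function(coefficients, std_errors, p_values,
                                  r_squared, n, model_kind, quantile = NA_real_) {
  structure(list(coefficients = coefficients, std_errors = std_errors,
                 p_values = p_values, r_squared = r_squared, n = n,
                 model_kind = model_kind, quantile = quantile),
            class = "cadi_regression")
}

#' Fit the linear regression model (OLS)
#'
#' Ordinary least squares with conventional (homoskedastic) standard
#' errors, two-sided t-test p-values, and the centered coefficient of
#' determination.
#'
#' @param design List from [build_design()] (or any list with `X`, `y`).
#' @return A `cadi_regression` with `model_kind = "LRM"`.
#' @export
fit_lrm <- function(design) {
  X <- design$X
  y <- design$y
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more rows than columns to fit OLS")
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(0, diag(xtx_inv)) * sigma2)
  names(se) <- colnames(X)
  tval <- b / se
  pval <- 2 * pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  new_regression_result(b, se, pval, r2, n, "LRM")
}

check_loss <- function(residuals, q) {
  sum(residuals * (q - (residuals < 0)))
}

# Quantile-regression point estimate: IRLS on the check loss with an
# interpolation polish (the exact minimizer passes through p observations).
qr_coef <- function(X, y, q, maxit = 500L, tol = 1e-8) {
  n <- nrow(X)
  p <- ncol(X)
  if (p == 1L && all(X[, 1L] == 1)) {
    # intercept-only: the check-loss minimizer is the sample q-quantile;
    # at q = 0.5 and even n we take the midpoint of the central pair
    b <- if (q == 0.5) median(y) else unname(quantile(y, q, type = 1))
    return(setNames(b, colnames(X)))
  }
  b <- qr.coef(qr(X), y)
  eps <- 1e-9 * max(1, mean(abs(y)))
  best <- b
  best_loss <- check_loss(y - X %*% b, q)
  delta <- Inf
  polish <- function(b0, loss0) {
    # the exact minimizer interpolates p observations: refit through the
    # p smallest-residual rows and keep the result if it does not worsen
    r0 <- as.numeric(y - X %*% b0)
    idx <- order(abs(r0))[seq_len(p)]
    if (qr(X[idx, , drop = FALSE])$rank == p) {
      b_v <- qr.coef(qr(X[idx, , drop = FALSE]), y[idx])
      if (!anyNA(b_v) && check_loss(y - X %*% b_v, q) <= loss0 + 1e-12) {
        return(b_v)
      }
    }
    b0
  }
  stale <- 0L
  for (it in seq_len(maxit)) {
    r <- as.numeric(y - X %*% b)
    w <- ifelse(r > 0, q, 1 - q) / pmax(abs(r), eps)
    b_new <- lm.wfit(X, y, w)$coefficients
    if (anyNA(b_new)) break
    delta <- max(abs(b_new - b))
    b <- b_new
    loss <- check_loss(y - X %*% b, q)
    if (loss < best_loss - 1e-10 * (1 + abs(best_loss))) {
      stale <- 0L
    } else {
      stale <- stale + 1L   # IRLS zigzags near a vertex; stop when stalled
    }
    if (loss < best_loss) {
      best <- b
      best_loss <- loss
    }
    if (delta < tol * (1 + max(abs(b))) || stale >= 10L) break
  }
  b <- polish(best, best_loss)
  # verified convergence: no coordinate perturbation improves the check loss
  l0 <- check_loss(y - X %*% b, q)
  step <- 1e-6 * pmax(1, abs(b))
  for (j in seq_len(p)) {
    for (sgn in c(-1, 1)) {
      b_try <- b
      b_try[j] <- b_try[j] + sgn * step[j]
      if (check_loss(y - X %*% b_try, q) < l0 - 1e-7 * (1 + abs(l0))) {
        stop("quantile regression did not converge after ", maxit,
             " IRLS iterations (last step size ", format(delta),
             ", descent direction remains in coordinate ",
             colnames(X)[j], ")")
      }
    }
  }
  b
}

#' Fit the quantile regression model
#'
#' Minimizes the check loss sum_i rho_q(y_i - x_i'b) by iteratively
#' reweighted least squares with an interpolation polish; at the default
#' q = 0.5 this is median regression. Standard errors are estimated by a
#' nonparametric bootstrap over rows (fixed seed, `nboot` resamples), with
#' normal-approximation two-sided p-values.
#'
#' @param design List from [build_design()].
#' @param q Quantile in (0, 1); default 0.5 (the conditional median).
#' @param nboot Bootstrap resamples for standard errors (default 500; 0
#'   skips the bootstrap and reports NA standard errors).
#' @param seed Bootstrap seed.
#' @return A `cadi_regression` with `model_kind = "QRM"`; `r_squared` is NA.
#' @export
fit_qrm <- function(design, q = 0.5, nboot = 500L, seed = 1L) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  X <- design$X
  y <- design$y
  n <- nrow(X)
  b <- qr_coef(X, y, q)
  se <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  pval <- se
  if (nboot > 0L) {
    boots <- with_seed(seed, {
      out <- matrix(NA_real_, nboot, ncol(X))
      for (i in seq_len(nboot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bi <- tryCatch(qr_coef(X[idx, , drop = FALSE], y[idx], q),
                       error = function(e) NULL)
        if (!is.null(bi)) out[i, ] <- bi
      }
      out
    })
    se <- apply(boots, 2L, sd, na.rm = TRUE)
    names(se) <- colnames(X)
    pval <- 2 * pnorm(-abs(b / se))
  }
  new_regression_result(b, se, pval, NA_real_, n, "QRM", quantile = q)
}

#' @export
print.cadi_regression <- function(x, ...) {
  cat(x$model_kind,
      if (x$model_kind == "QRM") sprintf("(q = %g)", x$quantile) else "",
      "- n =", x$n,
      if (is.finite(x$r_squared)) sprintf(", R-squared = %.3f", x$r_squared),
      "\n")
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors,
                    p_value = x$p_values)
  tab$sig <- significance_stars(x$p_values)
  print(cbind(round(tab[1:3], 4), sig = tab$sig))
  invisible(x)
}

#' @export
coef.cadi_regression <- function(object, ...) object$coefficients

#' @export
summary.cadi_regression <- function(object, ...) object

#' Significance stars following the usual convention
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars ("" when not significant or NA).
#' @export
significance_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Split a panel into low- and high-GDP subgroups
#'
#' The threshold is the mean per-capita GDP over all region-year rows (the
#' multi-year national average). Each region is assigned wholly by its own
#' multi-year mean: below the threshold to subgroup 1 (low GDP), otherwise
#' (ties included) to subgroup 2 (high GDP). Regions are never split across
#' groups.
#'
#' @param panel Data frame with `region` and `gdp_pc` columns.
#' @return List with `subgroup1`, `subgroup2` (row subsets of `panel`) and
#'   `threshold`.
#' @export
split_by_gdp <- function(panel) {
  if (!"gdp_pc" %in% names(panel)) stop("panel has no 'gdp_pc' column")
  if (anyNA(panel$gdp_pc) || any(panel$gdp_pc <= 0)) {
    stop("'gdp_pc' must be positive and complete")
  }
  threshold <- mean(panel$gdp_pc)
  region_mean <- tapply(panel$gdp_pc, panel$region, mean)
  low <- names(region_mean)[region_mean < threshold]
  high <- names(region_mean)[region_mean >= threshold]
  if (length(low) == 0L || length(high) == 0L) {
    warning("all regions fall on one side of the GDP threshold; ",
            "one subgroup is empty")
  }
  list(subgroup1 = panel[panel$region %in% low, , drop = FALSE],
       subgroup2 = panel[panel$region %in% high, , drop = FALSE],
       threshold = threshold)
}

fit_or_null <- function(panel, kind, q, nboot, seed) {
  if (nrow(panel) == 0L) return(NULL)
  design <- build_design(panel)
  if (kind == "LRM") fit_lrm(design) else fit_qrm(design, q, nboot, seed)
}

#' Full association analysis: LRM and QRM, overall and by GDP subgroup
#'
#' Fits ordinary least squares and median (quantile) regression of the
#' index on the eight covariates plus year dummies, on the full panel and
#' on the low-/high-GDP subgroups, and assembles a six-column report grid
#' with significance stars.
#'
#' @param panel Data frame with region, year, the eight covariates,
#'   `gdp_pc`, and `cadi`.
#' @param quantile Quantile for the QRM fits (default 0.5).
#' @param nboot Bootstrap resamples for QRM standard errors.
#' @param seed Seed for the QRM bootstrap.
#' @return Object of class `cadi_analysis`: list with `results` (nested
#'   list LRM/QRM x overall/subgroup1/subgroup2), `table` (formatted grid),
#'   `threshold`, `n`.
#' @export
run_full_analysis <- function(panel, quantile = 0.5, nboot = 500L, seed = 1L) {
  groups <- split_by_gdp(panel)
  panels <- list(overall = panel, subgroup1 = groups$subgroup1,
                 subgroup2 = groups$subgroup2)
  results <- list(
    LRM = lapply(panels, fit_or_null, kind = "LRM", q = quantile,
                 nboot = nboot, seed = seed),
    QRM = lapply(panels, fit_or_null, kind = "QRM", q = quantile,
                 nboot = nboot, seed = seed)
  )
  terms <- names(results$LRM$overall$coefficients)
  terms <- c(setdiff(terms, "(Intercept)"), "(Intercept)")
  fmt <- function(res) {
    if (is.null(res)) return(setNames(rep(NA_character_, length(terms)), terms))
    est <- res$coefficients[terms]
    stars <- significance_stars(res$p_values[terms])
    setNames(trimws(paste(sprintf("%.3f", est), stars)), terms)
  }
  grid <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (kind in c("LRM", "QRM")) {
    for (g in names(panels)) {
      grid[[paste(kind, g, sep = ".")]] <- unname(fmt(results[[kind]][[g]]))
    }
  }
  extra <- data.frame(
    term = c("R-squared", "n"),
    `LRM.overall` = c(sprintf("%.3f", results$LRM$overall$r_squared),
                      as.character(results$LRM$overall$n)),
    `LRM.subgroup1` = c(if (is.null(results$LRM$subgroup1)) NA else
                          sprintf("%.3f", results$LRM$subgroup1$r_squared),
                        if (is.null(results$LRM$subgroup1)) NA else
                          as.character(results$LRM$subgroup1$n)),
    `LRM.subgroup2` = c(if (is.null(results$LRM$subgroup2)) NA else
                          sprintf("%.3f", results$LRM$subgroup2$r_squared),
                        if (is.null(results$LRM$subgroup2)) NA else
                          as.character(results$LRM$subgroup2$n)),
    `QRM.overall` = c("-", as.character(results$QRM$overall$n)),
    `QRM.subgroup1` = c("-", if (is.null(results$QRM$subgroup1)) NA else
                          as.character(results$QRM$subgroup1$n)),
    `QRM.subgroup2` = c("-", if (is.null(results$QRM$subgroup2)) NA else
                          as.character(results$QRM$subgroup2$n)),
    stringsAsFactors = FALSE
  )
  grid <- rbind(grid, extra)
  structure(list(results = results, table = grid,
                 threshold = groups$threshold,
                 n = c(overall = nrow(panel),
                       subgroup1 = nrow(groups$subgroup1),
                       subgroup2 = nrow(groups$subgroup2))),
            class = "cadi_analysis")
}

#' @export
print.cadi_analysis <- function(x, ...) {
  cat("Association analysis (GDP threshold =",
      format(x$threshold, big.mark = ","), ")\n")
  cat("Significance: * p<0.05, ** p<0.01, *** p<0.001\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
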