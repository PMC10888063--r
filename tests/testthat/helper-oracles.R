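# Independent brute-force oracles used to check the vectorized implementation.

# window co-occurrence counts of every word with any target, by naive loops
oracle_cooccur <- function(texts, targets, window) {
  counts <- new.env(parent = emptyenv())
  bump <- function(w) assign(w, (if (exists(w, counts)) get(w, counts) else 0) + 1, counts)
  for (txt in texts) {
    toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
    surf <- sub("/[^/]*$", "", toks)
    tpos <- which(surf %in% targets)
    for (tp in tpos) {
      for (j in seq_along(surf)) {
        if (j != tp && abs(j - tp) <= window) bump(surf[j])
      }
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) numeric() else out
}

# naive triple-loop CADI
oracle_cadi <- function(panel, weights, tau) {
  out <- list()
  for (y in sort(unique(panel$year))) {
    py <- panel[panel$year == y, ]
    wy <- weights[weights$year == y, ]
    for (r in sort(unique(py$region))) {
      total <- 0
      for (i in seq_len(nrow(wy))) {
        word <- wy$word[i]
        cell <- py[py$word == word, ]
        v <- cell$gamma_bar[cell$region == r]
        lo <- min(cell$gamma_bar)
        hi <- max(cell$gamma_bar)
        frac <- if (hi > lo) (v - lo) / (hi - lo) else 0.5
        total <- total + (frac * tau + (100 - tau)) * wy$w[i]
      }
      out[[length(out) + 1L]] <- data.frame(region = r, year = y, cadi = total)
    }
  }
  do.call(rbind, out)
}

oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(choose(table(x), 2))
  t2 <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - t1) * (n0 - t2))
}

oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# normal-equations OLS
oracle_ols <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

oracle_check_loss <- function(r, q) sum(r * (q - (r < 0)))

# random balanced population-adjusted panel plus weights summing to 1
make_balanced_panel <- function(n_regions, n_words, years, seed) {
  set.seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  words <- sprintf("w%02d", seq_len(n_words))
  panel <- expand.grid(region = regions, word = words, year = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel$gamma_bar <- runif(nrow(panel), 0, 1e-4)
  phi <- matrix(runif(n_words * length(years), 0.1, 2),
                n_words, length(years))
  weights <- expand.grid(word = words, year = years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  weights$w <- as.numeric(sweep(phi, 2, colSums(phi), "/"))
  list(panel = panel, weights = weights)
}
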