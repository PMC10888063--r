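test_that("yearly_average is the mean over observed days in the year", {
  dts <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  expect_equal(yearly_average(rep(7, length(dts)), dts, 2020), 7)
  expect_equal(yearly_average(1:4, as.Date("2019-03-01") + 0:3, 2019), 2.5)
  expect_error(yearly_average(1:4, as.Date("2019-03-01") + 0:3, 2020,
                              label = "w1"), "no observations in year 2020")
  # 10% missing days: equals brute-force sum/count over present days
  set.seed(2)
  keep <- runif(length(dts)) > 0.1
  v <- runif(sum(keep), 0, 100)
  expect_equal(yearly_average(v, dts[keep], 2020), sum(v) / sum(keep))
  # aggregation helper agrees with the scalar operation
  tr <- data.frame(region = "R1", word = "w1", date = dts[keep], value = v)
  agg <- aggregate_regional_trends(tr)
  expect_equal(agg$gamma, yearly_average(v, dts[keep], 2020))
})

test_that("weights are relevance-times-volume shares summing to one", {
  pod <- data.frame(word = c("a", "b"), alpha = c(1, 1))
  nat <- data.frame(word = c("a", "b"), year = 2020L, beta = c(2, 2))
  expect_equal(compute_weights(pod, nat)$w, c(0.5, 0.5))
  pod2 <- data.frame(word = c("a", "b"), alpha = c(1, 3))
  nat2 <- data.frame(word = c("a", "b"), year = 2020L, beta = c(1, 1))
  expect_equal(compute_weights(pod2, nat2)$w, c(0.25, 0.75))

  # 20 random words over 3 years: matches brute-force phi / sum(phi)
  set.seed(4)
  words <- sprintf("w%02d", 1:20)
  pod3 <- data.frame(word = words, alpha = runif(20))
  nat3 <- expand.grid(word = words, year = 2018:2020,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nat3$beta <- runif(nrow(nat3), 0, 50)
  wt <- compute_weights(pod3, nat3)
  for (y in 2018:2020) {
    wy <- wt[wt$year == y, ]
    phi <- pod3$alpha[match(wy$word, pod3$word)] *
      nat3$beta[match(paste(wy$word, y), paste(nat3$word, nat3$year))]
    expect_equal(wy$w, phi / sum(phi))
    expect_equal(sum(wy$w), 1, tolerance = 1e-12)
  }

  # zero total phi in a year is rejected
  nat4 <- data.frame(word = c("a", "b"), year = 2020L, beta = c(0, 0))
  expect_error(compute_weights(pod, nat4), "irrelevant or untrended")
  # a word with no beta for a year is rejected
  expect_error(compute_weights(pod, nat[1, ]), "missing national trend")
})

test_that("population adjustment divides elementwise by population", {
  panel <- data.frame(region = "R1", word = "w1", year = 2020L, gamma = 100)
  pop <- data.frame(region = "R1", year = 2020L, population = 1e7)
  expect_equal(population_adjust(panel, pop)$gamma_bar, 1e-5)

  set.seed(6)
  panel2 <- expand.grid(region = c("R1", "R2", "R3"), word = c("a", "b"),
                        year = 2019:2020, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  panel2$gamma <- runif(nrow(panel2), 0, 100)
  pop2 <- expand.grid(region = c("R1", "R2", "R3"), year = 2019:2020,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop2$population <- runif(nrow(pop2), 1e6, 1e8)
  adj <- population_adjust(panel2, pop2)
  for (i in seq_len(nrow(adj))) {
    d <- pop2$population[pop2$region == adj$region[i] & pop2$year == adj$year[i]]
    expect_equal(adj$gamma_bar[i], adj$gamma[i] / d)
  }
  # equal populations preserve the gamma ordering
  pop3 <- pop2; pop3$population <- 5e7
  adj3 <- population_adjust(panel2, pop3)
  expect_equal(order(adj3$gamma), order(adj3$gamma_bar))
  expect_error(population_adjust(panel2, pop2[-1, ]), "missing population")
  pop4 <- pop2; pop4$population[1] <- 0
  expect_error(population_adjust(panel2, pop4), "nonpositive population")
})

test_that("efficacy score maps the envelope onto [100 - tau, 100]", {
  expect_equal(efficacy_score(0, 0, 1, tau = 40), 60)
  expect_equal(efficacy_score(1, 0, 1, tau = 40), 100)
  expect_equal(efficacy_score(0.5, 0, 1, tau = 40), 80)
  # degenerate envelope: fraction 1/2
  expect_equal(efficacy_score(3, 3, 3, tau = 40), 80)
  expect_error(efficacy_score(2, 0, 1, tau = 40), "outside")
  expect_error(efficacy_score(0.5, 0, 1, tau = 0), "tau")
  expect_error(efficacy_score(0.5, 0, 1, tau = 101), "tau")
})

test_that("compute_cadi equals the triple-loop oracle on random panels", {
  mk <- make_balanced_panel(8, 10, 2018:2020, seed = 13)
  got <- compute_cadi(mk$panel, mk$weights, tau = 40)
  expect_true(all(got$cadi >= 60 - 1e-9 & got$cadi <= 100 + 1e-9))
  want <- oracle_cadi(mk$panel, mk$weights, tau = 40)
  merged <- merge(got, want, by = c("region", "year"))
  expect_equal(merged$cadi.x, merged$cadi.y, tolerance = 1e-12)
})

test_that("compute_cadi validates its panel", {
  mk <- make_balanced_panel(4, 3, 2020, seed = 1)
  expect_error(compute_cadi(mk$panel[-1, ], mk$weights), "unbalanced")
  expect_error(compute_cadi(mk$panel, mk$weights[-1, ]), "weights missing")
  one <- mk$panel[mk$panel$region == "R01", ]
  expect_error(compute_cadi(one, mk$weights), "at least 2 regions")
  nog <- mk$panel; nog$gamma_bar <- NULL
  expect_error(compute_cadi(nog, mk$weights), "gamma_bar")
})

test_that("raising one region's adjusted trend never lowers its index", {
  mk <- make_balanced_panel(5, 4, 2020, seed = 17)
  base <- compute_cadi(mk$panel, mk$weights)
  i <- which(mk$panel$region == "R03" & mk$panel$word == "w02")
  cell <- mk$panel[mk$panel$word == "w02", ]
  hi <- max(cell$gamma_bar)
  for (v in seq(mk$panel$gamma_bar[i], hi, length.out = 5)) {
    p2 <- mk$panel
    p2$gamma_bar[i] <- v
    # keep the envelope fixed: v stays within [min, max] of the other regions
    got <- compute_cadi(p2, mk$weights)
    expect_gte(got$cadi[got$region == "R03"] + 1e-12,
               base$cadi[base$region == "R03"])
    base <- got
  }
})

test_that("penetration adjustment multiplies by the adjacent-year ratio", {
  tab <- data.frame(region = rep(c("A", "B"), each = 3),
                    year = rep(2018:2020, 2),
                    cadi = c(80, 90, 70, 61, 99, 75),
                    cadi_adjusted = NA_real_)
  # constant penetration: adjusted equals raw
  pen_c <- data.frame(year = 2018:2020, penetration = 0.6)
  expect_equal(penetration_adjust(tab, pen_c)$cadi_adjusted, tab$cadi)
  # 10% growth: first year ratio 1, later years scaled
  pen <- data.frame(year = 2018:2020, penetration = 0.6 * 1.1^(0:2))
  adj <- penetration_adjust(tab, pen)
  expect_equal(adj$cadi_adjusted[adj$year == 2018], c(80, 61))
  expect_equal(adj$cadi_adjusted[adj$year == 2019], c(90, 99) * 1.1)
  expect_equal(adj$cadi_adjusted[adj$year == 2020], c(70, 75) * 1.1)
  expect_equal(penetration_adjust(tab[tab$year == 2019, ],
                                  pen)$cadi_adjusted, c(90, 99))
  expect_error(penetration_adjust(tab, pen[-1, ]), "penetration missing")
  pen_bad <- pen; pen_bad$penetration[1] <- 0
  expect_error(penetration_adjust(tab, pen_bad), "> 0")
})

test_that("cadi = 80 with a 1.1 penetration ratio adjusts to 88", {
  tab <- data.frame(region = "A", year = 2019:2020, cadi = c(80, 80),
                    cadi_adjusted = NA_real_)
  pen <- data.frame(year = 2019:2020, penetration = c(0.50, 0.55))
  adj <- penetration_adjust(tab, pen)
  expect_equal(adj$cadi_adjusted, c(80, 88))
})
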