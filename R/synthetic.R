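#' Covariate names used by the association layer
#'
#' Disposable income (DI), consumer price index (CPI), consumption growth
#' rate (CGR), import-export index (IE), average cost of patients (ACP),
#' regional health expenditure (RHE), rate of doctors (RD), and rate of
#' unemployment (RU).
#'
#' @return Character vector of the eight covariate names.
#' @export
covariate_names <- function() {
  c("DI", "CPI", "CGR", "IE", "ACP", "RHE", "RD", "RU")
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: panel dimensions, corpus size,
#' noise level, and the signed effects of the covariates on the latent
#' negative-mental-health severity. Defaults mirror the scale of the real
#' study: 31 provincial regions observed 2016-2021.
#'
#' @param n_regions Number of regions (>= 2; min-max scoring needs at least
#'   two regions).
#' @param years Integer vector of consecutive calendar years.
#' @param n_words Number of planted severity-related words (the true POD).
#' @param n_docs Number of corpus documents.
#' @param noise_sd Standard deviation of the Gaussian noise added to daily
#'   trends and to the latent severity equation.
#' @param effect_sizes Named numeric vector of signed covariate effects on
#'   latent severity; names must be a subset of [covariate_names()]. The
#'   default plants a negative import-export effect and a positive
#'   average-cost-of-patients effect.
#' @param seed Integer seed; every generator stream derives from it.
#' @param n_background Number of background (non-severity) vocabulary words.
#' @param cooccur_excess Probability in \[0, 1\] that a context slot adjacent
#'   to a target word is filled with a planted word rather than a draw from
#'   the whole candidate pool.
#' @param lambda Loading of latent severity on per-capita search intensity.
#' @param n_respondents Survey respondents per region.
#' @param pen_start Internet penetration in the first year (proportion).
#' @param pen_growth Annual relative growth of penetration.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_regions = 31L, years = 2016:2021,
                            n_words = 10L, n_docs = 2000L, noise_sd = 0.1,
                            effect_sizes = c(IE = -1, ACP = 1), seed = 1L,
                            n_background = 20L, cooccur_excess = 0.8,
                            lambda = 1, n_respondents = 200L,
                            pen_start = 0.50, pen_growth = 0.05) {
  years <- as.integer(unlist(years))
  effect_sizes <- unlist(effect_sizes)
  if (length(years) == 0L) stop("'years' must be nonempty")
  if (any(diff(years) != 1L)) stop("'years' must be consecutive calendar years")
  if (n_regions < 2L) stop("'n_regions' must be >= 2 (min-max scoring needs at least two regions)")
  if (n_words < 1L) stop("'n_words' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (cooccur_excess < 0 || cooccur_excess > 1) stop("'cooccur_excess' must lie in [0, 1]")
  if (length(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), covariate_names())
    if (length(bad)) {
      stop("unknown covariate name(s) in 'effect_sizes': ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(
    n_regions = as.integer(n_regions), years = years,
    n_words = as.integer(n_words), n_docs = as.integer(n_docs),
    noise_sd = noise_sd, effect_sizes = effect_sizes,
    seed = as.integer(seed), n_background = as.integer(n_background),
    cooccur_excess = cooccur_excess, lambda = lambda,
    n_respondents = as.integer(n_respondents),
    pen_start = pen_start, pen_growth = pen_growth
  ), class = "scenario_config")
}

region_ids <- function(config) sprintf("R%02d", seq_len(config$n_regions))

#' Vocabulary specification of the synthetic corpus
#'
#' The corpus is built from tagged pseudo-tokens (`surface/pos`) so that the
#' part-of-speech and character-length filters of the dictionary builder are
#' exercised without any language-specific segmenter. Targets and planted
#' words are nouns/adjectives of length >= 2; filler tokens (verbs, a
#' one-character noun, stopwords, a singleton rare word) exist only to be
#' removed by the filters.
#'
#' @param config A [scenario_config()].
#' @return List with elements `targets`, `planted`, `background`,
#'   `stopwords`, `fillers`, `window`.
#' @export
corpus_vocabulary <- function(config) {
  np <- config$n_words
  nb <- config$n_background
  planted <- sprintf("dread%02d", seq_len(np))
  planted_pos <- rep(c("n", "a"), length.out = np)
  background <- sprintf("field%02d", seq_len(nb))
  background_pos <- rep(c("n", "a"), length.out = nb)
  list(
    targets = c(anxiety = "n", depression = "n"),
    planted = setNames(planted_pos, planted),
    background = setNames(background_pos, background),
    stopwords = setNames(c("n", "n"), c("thing", "stuff")),
    fillers = c(went = "v", took = "v", z = "n", comet = "n"),
    window = 2L
  )
}

tag_token <- function(surface, pos) paste0(surface, "/", pos)

#' Generate a synthetic tagged-text corpus with planted co-occurrence
#'
#' Emits `n_docs` short documents. Around half the documents contain one of
#' the target words; context slots within `window` tokens of the target are
#' filled with a planted word with probability `cooccur_excess`, otherwise
#' with a uniform draw from the planted-plus-background pool, so planted
#' words co-occur with targets at a controlled excess rate (at excess 0 the
#' two pools are exchangeable). Document character lengths span both sides
#' of the 15-character corpus filter.
#'
#' @param config A [scenario_config()].
#' @return A data.frame of class `cadi_corpus` with columns `id`,
#'   `platform`, `date`, `text`, and a `"vocabulary"` attribute.
#' @export
gen_corpus <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_docs < 1L) stop("empty corpus: 'n_docs' must be >= 1")
  voc <- corpus_vocabulary(config)
  pool <- c(names(voc$planted), names(voc$background))
  pool_pos <- c(unname(voc$planted), unname(voc$background))
  filler <- c(names(voc$stopwords), names(voc$fillers)[1:3])
  filler_pos <- c(unname(voc$stopwords), unname(voc$fillers)[1:3])
  win <- voc$window
  excess <- config$cooccur_excess

  with_seed(config$seed, {
    n <- config$n_docs
    texts <- character(n)
    for (d in seq_len(n)) {
      ntok <- sample(1:12, 1L)
      surf <- character(ntok)
      pos <- character(ntok)
      # non-target slots: mostly candidate-pool words, some filler
      fill_slot <- function() {
        if (runif(1) < 0.15) {
          j <- sample(length(filler), 1L)
          c(filler[j], filler_pos[j])
        } else {
          j <- sample(length(pool), 1L)
          c(pool[j], pool_pos[j])
        }
      }
      has_target <- ntok >= 3L && runif(1) < 0.5
      if (has_target) {
        tpos <- sample(ntok, 1L)
        tw <- sample(names(voc$targets), 1L)
        surf[tpos] <- tw
        pos[tpos] <- voc$targets[[tw]]
        for (j in seq_len(ntok)[-tpos]) {
          if (abs(j - tpos) <= win && runif(1) < excess) {
            k <- sample(length(voc$planted), 1L)
            surf[j] <- names(voc$planted)[k]
            pos[j] <- voc$planted[[k]]
          } else {
            sl <- fill_slot()
            surf[j] <- sl[1L]
            pos[j] <- sl[2L]
          }
        }
      } else {
        for (j in seq_len(ntok)) {
          sl <- fill_slot()
          surf[j] <- sl[1L]
          pos[j] <- sl[2L]
        }
      }
      texts[d] <- paste(tag_token(surf, pos), collapse = " ")
    }
    # one singleton rare word, removed downstream by the frequency filter
    texts[1L] <- paste(texts[1L], tag_token("comet", "n"))
    out <- data.frame(
      id = sprintf("doc%05d", seq_len(n)),
      platform = sample(c("weibo", "douban", "zhihu"), n, replace = TRUE),
      date = as.Date("2020-01-01") + sample(0:181, n, replace = TRUE),
      text = texts,
      stringsAsFactors = FALSE
    )
    attr(out, "vocabulary") <- voc
    class(out) <- c("cadi_corpus", "data.frame")
    out
  })
}

#' True relevance of the planted words
#'
#' Decreasing sequence in (0, 1\]: the first planted word is most related to
#' the targets. Background words have relevance 0 by construction.
#'
#' @param config A [scenario_config()].
#' @return Named numeric vector over the planted words.
#' @export
true_relevance <- function(config) {
  voc <- corpus_vocabulary(config)
  setNames(seq(0.95, 0.50, length.out = config$n_words), names(voc$planted))
}

#' Generate covariates, latent severity, and survey microdata
#'
#' Covariates are independent standard-normal region-year draws; per-capita
#' GDP is log-normal across regions with mild annual growth. Latent
#' severity is linear-Gaussian: s = sum_k effect_k * x_k + N(0, noise_sd).
#' Survey respondents in the reference year draw a binary mental-disorder
#' indicator with probability increasing in severity, with positive
#' log-normal sampling weights.
#'
#' @param config A [scenario_config()].
#' @param n_respondents Respondents per region (defaults to the config).
#' @return List with `covariates` (region, year, the eight covariates,
#'   `gdp_pc`), `severity` (region, year, `s`), `survey` (region, weight,
#'   disorder) and `survey_year`.
#' @export
gen_covariates_survey <- function(config, n_respondents = config$n_respondents) {
  stopifnot(inherits(config, "scenario_config"))
  eff <- config$effect_sizes
  bad <- setdiff(names(eff), covariate_names())
  if (length(bad)) stop("unknown covariate name(s): ", paste(bad, collapse = ", "))
  regions <- region_ids(config)
  years <- config$years
  grid <- expand.grid(region = regions, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$region, grid$year), , drop = FALSE]
  rownames(grid) <- NULL
  n <- nrow(grid)
  with_seed(config$seed + 1L, {
    X <- matrix(rnorm(n * 8L), nrow = n, dimnames = list(NULL, covariate_names()))
    gdp_base <- exp(rnorm(length(regions), log(6e4), 0.35))
    names(gdp_base) <- regions
    gdp_pc <- gdp_base[grid$region] * 1.06^(grid$year - min(years))
    s <- if (length(eff)) {
      as.numeric(X[, names(eff), drop = FALSE] %*% unname(eff))
    } else {
      rep(0, n)
    }
    if (config$noise_sd > 0) s <- s + rnorm(n, 0, config$noise_sd)
    covariates <- cbind(grid, as.data.frame(X), gdp_pc = unname(gdp_pc))
    severity <- cbind(grid, s = s)
    survey_year <- years[which.min(abs(years - 2020L))]
    sy <- severity[severity$year == survey_year, ]
    s_z <- as.numeric(scale(sy$s))
    if (any(!is.finite(s_z))) s_z <- rep(0, nrow(sy))  # zero-variance severity
    prob <- plogis(-2 + 1.5 * s_z)
    survey <- data.frame(
      region = rep(sy$region, each = n_respondents),
      weight = rlnorm(nrow(sy) * n_respondents, 0, 0.5),
      disorder = rbinom(nrow(sy) * n_respondents, 1L,
                        rep(prob, each = n_respondents)),
      stringsAsFactors = FALSE
    )
    list(covariates = covariates, severity = severity, survey = survey,
         survey_year = survey_year)
  })
}

#' Generate regional and national search-trend series
#'
#' The per-capita search intensity of word i in region r on a day of year y
#' is `base(i) + lambda * s(r, y) * relevance(i) + N(0, noise_sd)`,
#' truncated at zero. The emitted regional trend is that intensity times
#' the region's population relative to the year's mean population
#' (`volume_scaling = "population"`, the default when a population table is
#' supplied): search volume scales with the number of people searching, and
#' dividing by population downstream recovers the per-capita signal. With
#' `volume_scaling = "none"` the trend equals the intensity itself, so with
#' `lambda = 0` and `noise_sd = 0` every region shares an identical series.
#' The national series is the population-weighted (or plain, if unscaled)
#' mean of the regional series.
#'
#' @param config A [scenario_config()].
#' @param severity Data frame (region, year, s) as from
#'   [gen_covariates_survey()].
#' @param relevance Named numeric vector in \[0, 1\]: per-word loading of
#'   severity on search intensity.
#' @param population Optional population table (region, year, population);
#'   required for `volume_scaling = "population"`.
#' @param volume_scaling `"population"` or `"none"`; defaults to
#'   `"population"` when `population` is supplied, else `"none"`.
#' @param resolution `"daily"` (one row per calendar day) or `"yearly"`
#'   (one row per year dated January 1, with the noise standard deviation
#'   scaled by 1/sqrt(days) to match a daily average).
#' @return List with `regional` (region, word, date, value) and `national`
#'   (word, date, value) data frames.
#' @export
gen_trend_panel <- function(config, severity, relevance, population = NULL,
                            volume_scaling = if (is.null(population)) "none" else "population",
                            resolution = c("daily", "yearly")) {
  stopifnot(inherits(config, "scenario_config"))
  resolution <- match.arg(resolution)
  volume_scaling <- match.arg(volume_scaling, c("population", "none"))
  if (is.null(severity) || nrow(severity) == 0L) stop("empty severity table")
  if (is.null(names(relevance)) || any(relevance < 0 | relevance > 1)) {
    stop("'relevance' must be a named vector with values in [0, 1]")
  }
  if (volume_scaling == "population" && is.null(population)) {
    stop("'population' table required for volume_scaling = \"population\"")
  }
  words <- names(relevance)
  years <- config$years

  dates_of_year <- function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
  }

  with_seed(config$seed + 2L, {
    base_i <- setNames(runif(length(words), 30, 70), words)
    sev <- data.table::as.data.table(severity)

    regional <- vector("list", length(years))
    national <- vector("list", length(years))
    for (k in seq_along(years)) {
      y <- years[k]
      dts <- if (resolution == "daily") dates_of_year(y) else as.Date(sprintf("%d-01-01", y))
      eff_sd <- if (resolution == "daily") config$noise_sd else
        config$noise_sd / sqrt(length(dates_of_year(y)))
      g <- data.table::CJ(region = sort(unique(sev$region)), word = words,
                          date = dts, sorted = TRUE)
      g <- merge(g, sev[sev$year == y, c("region", "s")], by = "region")
      g[, rel := relevance[word]]
      g[, base := base_i[word]]
      g[, mu := base + config$lambda * s * rel]
      g[, value := mu + (if (eff_sd > 0) rnorm(.N, 0, eff_sd) else 0)]
      g[, value := pmax(0, value)]
      if (volume_scaling == "population") {
        popy <- population[population$year == y, c("region", "population")]
        if (!all(unique(g$region) %in% popy$region)) {
          stop("population table missing regions for year ", y)
        }
        g <- merge(g, popy, by = "region")
        g[, value := value * population / mean(popy$population)]
        g[, pop_w := population]
      } else {
        g[, pop_w := 1]
      }
      nat <- g[, .(value = sum(value * pop_w) / sum(pop_w)), by = .(word, date)]
      regional[[k]] <- g[, c("region", "word", "date", "value")]
      national[[k]] <- nat
    }
    regional <- data.table::rbindlist(regional)
    national <- data.table::rbindlist(national)
    data.table::setorder(regional, region, word, date)
    data.table::setorder(national, word, date)
    list(regional = as.data.frame(regional), national = as.data.frame(national))
  })
}

#' Generate population and Internet-penetration tables
#'
#' Regional populations are log-normal around 45 million persons (the scale
#' of Chinese provinces) with 0.5% annual growth; national Internet
#' penetration starts at `pen_start` and grows by `pen_growth` per year
#' (nondecreasing by default).
#'
#' @param config A [scenario_config()].
#' @param constant_penetration If TRUE the penetration series is flat at
#'   `pen_start`, so the year-over-year ratio is 1.
#' @return List with `population` (region, year, population) and
#'   `penetration` (year, penetration).
#' @export
gen_population_penetration <- function(config, constant_penetration = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  regions <- region_ids(config)
  years <- config$years
  with_seed(config$seed + 3L, {
    base <- rlnorm(length(regions), log(4.5e7), 0.6)
    pop <- expand.grid(region = regions, year = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pop <- pop[order(pop$region, pop$year), , drop = FALSE]
    rownames(pop) <- NULL
    pop$population <- base[match(pop$region, regions)] *
      1.005^(pop$year - min(years))
    growth <- if (constant_penetration) 0 else config$pen_growth
    pen <- data.frame(
      year = years,
      penetration = config$pen_start * (1 + growth)^(years - min(years))
    )
    list(population = pop, penetration = pen)
  })
}

#' Simulate a full synthetic study
#'
#' Runs every generator in dependency order: covariates and latent severity
#' first, then populations and penetration, then the trend panel driven by
#' severity and the planted words' true relevance, then the corpus.
#'
#' @param config A [scenario_config()].
#' @param trend_resolution Passed to [gen_trend_panel()].
#' @return List with elements `corpus`, `trends` (list regional/national),
#'   `population`, `penetration`, `covariates`, `survey`, `severity`,
#'   `relevance`, `survey_year`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config(),
                              trend_resolution = c("daily", "yearly")) {
  trend_resolution <- match.arg(trend_resolution)
  cs <- gen_covariates_survey(config)
  pp <- gen_population_penetration(config)
  rel <- true_relevance(config)
  trends <- gen_trend_panel(config, cs$severity, rel,
                            population = pp$population,
                            resolution = trend_resolution)
  corpus <- gen_corpus(config)
  list(corpus = corpus, trends = trends, population = pp$population,
       penetration = pp$penetration, covariates = cs$covariates,
       survey = cs$survey, severity = cs$severity, relevance = rel,
       survey_year = cs$survey_year, config = config)
}
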