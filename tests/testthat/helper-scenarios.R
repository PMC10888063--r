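# Shared small scenarios; expensive artifacts (trained embeddings) are
# built once per test run and memoised here.

tiny_config <- function(...) {
  defaults <- list(n_regions = 6L, years = 2019:2020, n_words = 4L,
                   n_docs = 400L, noise_sd = 0.05, n_respondents = 60L,
                   seed = 42L)
  args <- list(...)
  do.call(scenario_config, c(args, defaults[setdiff(names(defaults), names(args))]))
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .cache)) assign(key, build(), .cache)
  get(key, .cache)
}

# planted 2000-document corpus (co-occurrence excess 0.8) and its embeddings
planted_corpus <- function() {
  memo("planted_corpus", function() {
    gen_corpus(scenario_config(n_words = 6L, n_docs = 2000L,
                               cooccur_excess = 0.8, seed = 7L))
  })
}

planted_embeddings <- function() {
  memo("planted_embeddings", function() {
    toks <- tokenize_tagged(planted_corpus()$text)
    train_embeddings(split(toks$surface, toks$doc), seed = 7L)
  })
}
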