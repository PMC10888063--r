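#' Filter a corpus by character count and an optional relevance predicate
#'
#' Documents shorter than `min_chars` characters are discarded ("fewer than
#' `min_chars`" — a document of exactly `min_chars` characters is kept).
#' The optional predicate implements user-supplied topical relevance
#' screening; the default keeps everything.
#'
#' @param records Data frame with at least a `text` column (see
#'   [read_corpus_csv()] for the full schema).
#' @param min_chars Minimum character count (default 15).
#' @param relevance_filter Optional function `text -> logical`.
#' @return The retained records, input order preserved.
#' @export
filter_corpus <- function(records, min_chars = 15L, relevance_filter = NULL) {
  if (min_chars < 1L) stop("'min_chars' must be >= 1")
  if (!is.data.frame(records) || !"text" %in% names(records)) {
    stop("'records' must be a data frame with a 'text' column")
  }
  if (nrow(records) == 0L) return(records)
  keep <- nchar(records$text) >= min_chars
  if (!is.null(relevance_filter)) {
    keep <- keep & vapply(records$text, relevance_filter, logical(1), USE.NAMES = FALSE)
  }
  records[keep, , drop = FALSE]
}

#' Tokenize tagged text into (surface, pos, char_len) tokens
#'
#' The default tokenizer for `surface/pos` whitespace-delimited tagged
#' tokens. Real Chinese text would instead be segmented and POS-tagged by an
#' external tool (e.g. a Jieba adapter) producing the same token schema;
#' tokenization is deliberately pluggable via this one entry point.
#'
#' @param texts Character vector of tagged documents.
#' @return Data frame with columns `doc` (index), `surface`, `pos`,
#'   `char_len`.
#' @export
tokenize_tagged <- function(texts) {
  toks <- strsplit(trimws(texts), "[[:space:]]+")
  ns <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0L) {
    return(data.frame(doc = integer(), surface = character(),
                      pos = character(), char_len = integer(),
                      stringsAsFactors = FALSE))
  }
  surface <- sub("/[^/]*$", "", flat)
  pos <- sub("^.*/", "", flat)
  pos[!grepl("/", flat)] <- ""   # untagged token: empty POS
  data.frame(doc = rep(seq_along(texts), ns), surface = surface, pos = pos,
             char_len = nchar(surface), stringsAsFactors = FALSE)
}

#' Select candidate vocabulary by POS, length, stopword and frequency filters
#'
#' Keeps words that occur at least once with a whitelisted part of speech,
#' have surface length >= `min_char_len`, are not stopwords, and whose total
#' corpus frequency (over all occurrences) reaches `min_frequency`.
#'
#' @param tokens Data frame of tokens as from [tokenize_tagged()].
#' @param pos_whitelist POS tags to keep (default nouns "n" and adjectives
#'   "a").
#' @param min_char_len Minimum surface character count (default 2).
#' @param stopwords Character vector of words to drop.
#' @param min_frequency Minimum total corpus frequency (default 5).
#' @return Named integer vector mapping word to frequency, sorted by
#'   frequency descending then word.
#' @export
select_vocabulary <- function(tokens, pos_whitelist = c("n", "a"),
                              min_char_len = 2L, stopwords = character(),
                              min_frequency = 5L) {
  if (length(pos_whitelist) == 0L) {
    stop("'pos_whitelist' must be nonempty (an empty whitelist keeps nothing)")
  }
  if (min_char_len < 1L) stop("'min_char_len' must be >= 1")
  if (min_frequency < 1L) stop("'min_frequency' must be >= 1")
  if (nrow(tokens) == 0L) return(setNames(integer(), character()))
  freq <- table(tokens$surface)
  ok_pos <- unique(tokens$surface[tokens$pos %in% pos_whitelist])
  words <- names(freq)
  keep <- words %in% ok_pos &
    nchar(words) >= min_char_len &
    !(words %in% stopwords) &
    as.integer(freq) >= min_frequency
  out <- as.integer(freq[keep])
  names(out) <- words[keep]
  out[order(-out, names(out))]
}

#' Default stopword list for the synthetic tagged corpus
#' @return Character vector.
#' @export
default_stopwords <- function() c("thing", "stuff")

#' Train CBOW word embeddings
#'
#' Continuous-bag-of-words with negative sampling, trained single-threaded
#' with a dedicated RNG so results are reproducible for a fixed seed.
#' Words occurring fewer than `min_count` times are excluded from the
#' vocabulary.
#'
#' @param sentences List of character vectors (token surfaces per document).
#' @param dim Embedding dimension (default 100).
#' @param window Maximum context window half-width (default 5; shrunk
#'   uniformly at random per position, as in standard CBOW trainers).
#' @param epochs Training passes over the corpus (default 20).
#' @param seed Integer RNG seed.
#' @param min_count Minimum corpus frequency for a trainable word (default 2).
#' @param negative Number of negative samples per position (default 5).
#' @param learning_rate Initial learning rate, decayed linearly (default
#'   0.025).
#' @return Object of class `cadi_embeddings`: list with `vectors` (matrix,
#'   one row per word), `dim`, `vocabulary`.
#' @export
train_embeddings <- function(sentences, dim = 100L, window = 5L,
                             epochs = 20L, seed = 1L, min_count = 2L,
                             negative = 5L, learning_rate = 0.025) {
  if (length(sentences) == 0L) stop("empty corpus: no sentences to train on")
  if (dim < 1L || window < 1L || epochs < 1L) {
    stop("'dim', 'window' and 'epochs' must all be >= 1")
  }
  flat <- unlist(sentences, use.names = FALSE)
  if (length(flat) == 0L) stop("empty corpus: no tokens to train on")
  freq <- table(flat)
  freq <- freq[as.integer(freq) >= min_count]
  # frequency-descending vocabulary order (ties by word) for reproducibility
  vocab <- names(freq)[order(-as.integer(freq), names(freq))]
  if (length(vocab) < 2L) {
    stop("corpus too small: fewer than two words reach min_count = ", min_count)
  }
  counts <- as.integer(freq[vocab])
  ids <- lapply(sentences, function(s) {
    m <- match(s, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  ids <- ids[lengths(ids) >= 2L]
  if (length(ids) == 0L) {
    stop("corpus too small: no sentence has two in-vocabulary tokens, ",
         "so no context window can be formed")
  }
  mats <- cbow_train_cpp(ids, counts, as.integer(dim), as.integer(window),
                         as.integer(epochs), as.integer(negative),
                         learning_rate, as.integer(seed))
  rownames(mats$input) <- vocab
  rownames(mats$output) <- vocab
  structure(list(vectors = mats$input, context_vectors = mats$output,
                 dim = as.integer(dim), vocabulary = vocab),
            class = "cadi_embeddings")
}

#' @export
print.cadi_embeddings <- function(x, ...) {
  cat("CBOW embeddings:", length(x$vocabulary), "words x", x$dim, "dimensions\n")
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Relevance of a word to the target words
#'
#' alpha(word) is the mean, over the targets, of the cosine similarity
#' between the word's input vector and the target's context (output)
#' vector, clipped to \[0, 1\] so that downstream weights are nonnegative.
#' The input-output pairing measures first-order association — in
#' negative-sampling training the input-output dot product approximates the
#' pointwise mutual information between a word and the words it co-occurs
#' with — which is the notion of relevance a keyword dictionary needs.
#' (Input-input cosine instead measures second-order, similar-context
#' similarity and can be low or negative for words that directly co-occur
#' with a target.) When a word coincides with a target the similarity is
#' taken as 1 by convention.
#'
#' @param space A `cadi_embeddings` object.
#' @param word A single word.
#' @param targets Character vector of target words (e.g. "anxiety",
#'   "depression").
#' @return alpha in \[0, 1\].
#' @export
compute_relevance <- function(space, word, targets) {
  stopifnot(inherits(space, "cadi_embeddings"))
  absent <- setdiff(c(word, targets), space$vocabulary)
  if (length(absent)) {
    stop("token(s) absent from embedding vocabulary: ",
         paste(absent, collapse = ", "))
  }
  v <- space$vectors[word, ]
  sims <- vapply(targets, function(t) {
    if (identical(word, t)) return(1)
    cosine_sim(v, space$context_vectors[t, ])
  }, numeric(1))
  min(1, max(0, mean(sims)))
}

#' Build the Public Opinion Dictionary
#'
#' Full dictionary workflow: filter the corpus by length (and optional
#' relevance predicate), tokenize, select candidate words by POS, length,
#' stopword and frequency filters, train CBOW embeddings on the filtered
#' documents, score every candidate's relevance alpha to the target words,
#' and return candidates sorted by alpha (ties: frequency descending, then
#' word), optionally truncated by an alpha threshold and/or a size cap.
#'
#' @param corpus Data frame with a `text` column (tagged tokens).
#' @param targets Target words (default `c("anxiety", "depression")`).
#' @param min_chars,relevance_filter Passed to [filter_corpus()].
#' @param pos_whitelist,min_char_len,stopwords,min_frequency Passed to
#'   [select_vocabulary()].
#' @param dim,window,epochs,seed,min_count Passed to [train_embeddings()].
#' @param alpha_threshold Keep only words with alpha >= threshold (optional).
#' @param max_words Keep at most this many top words (optional).
#' @param tokenizer Function `texts -> token data frame`; default
#'   [tokenize_tagged()].
#' @return Data frame of class `cadi_pod` with columns `word`, `alpha`,
#'   `frequency`, sorted by alpha descending. May be empty (downstream
#'   weight computation rejects an empty dictionary).
#' @export
build_pod <- function(corpus, targets = c("anxiety", "depression"),
                      min_chars = 15L, relevance_filter = NULL,
                      pos_whitelist = c("n", "a"), min_char_len = 2L,
                      stopwords = default_stopwords(), min_frequency = 5L,
                      dim = 100L, window = 5L, epochs = 20L, seed = 1L,
                      min_count = 2L, alpha_threshold = NULL,
                      max_words = NULL, tokenizer = tokenize_tagged) {
  filtered <- filter_corpus(corpus, min_chars = min_chars,
                            relevance_filter = relevance_filter)
  if (nrow(filtered) == 0L) stop("no documents survive the corpus filter")
  tokens <- tokenizer(filtered$text)
  vocab <- select_vocabulary(tokens, pos_whitelist = pos_whitelist,
                             min_char_len = min_char_len,
                             stopwords = stopwords,
                             min_frequency = min_frequency)
  candidates <- setdiff(names(vocab), targets)
  sentences <- split(tokens$surface, tokens$doc)
  space <- train_embeddings(sentences, dim = dim, window = window,
                            epochs = epochs, seed = seed,
                            min_count = min_count)
  missing_targets <- setdiff(targets, space$vocabulary)
  if (length(missing_targets)) {
    stop("target word(s) absent from embedding vocabulary: ",
         paste(missing_targets, collapse = ", "))
  }
  candidates <- intersect(candidates, space$vocabulary)
  alpha <- vapply(candidates, function(w) compute_relevance(space, w, targets),
                  numeric(1))
  pod <- data.frame(word = candidates, alpha = unname(alpha),
                    frequency = as.integer(vocab[candidates]),
                    stringsAsFactors = FALSE)
  pod <- pod[order(-pod$alpha, -pod$frequency, pod$word), , drop = FALSE]
  if (!is.null(alpha_threshold)) pod <- pod[pod$alpha >= alpha_threshold, , drop = FALSE]
  if (!is.null(max_words)) pod <- head(pod, max_words)
  rownames(pod) <- NULL
  attr(pod, "embeddings") <- space
  class(pod) <- c("cadi_pod", "data.frame")
  pod
}

#' @export
print.cadi_pod <- function(x, n = 10L, ...) {
  cat("Public Opinion Dictionary:", nrow(x), "words\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}
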