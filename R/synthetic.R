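## Synthetic treebank generator.  The generator states a simple world:
## a Zipfian lexicon whose highest ranks are function words, sentences as
## random recursive dependency trees in which attachment can be biased
## toward function-word tokens (hub formation), sentence lengths from a
## truncated geometric law, and per-level vocabulary growth mirroring the
## 500 -> 4,000 vocabulary progression of graded learner curricula with a
## larger native reference.  Linear word order and projectivity are not
## modeled: the network depends only on the multiset of word pairs.

#' Generator configuration
#'
#' @param vocab_size Lexicon size (>= 10).
#' @param zipf_exponent Zipf rank exponent (> 0); rank-r probability is
#'   proportional to `r^-zipf_exponent`.
#' @param function_word_fraction Fraction of the top ranks flagged as
#'   function words (default 0.05).
#' @param hub_bias Extra attachment weight for function-word governors
#'   (>= 0; 0 = uniform attachment, default 5).
#' @param target_tokens Corpus size to emit (default 5000).
#' @param sentence_length `c(mean, min, max)` of the truncated geometric
#'   sentence-length law (default 12, 2, 40).
#' @param seed RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(vocab_size = 1000, zipf_exponent = 1,
                             function_word_fraction = 0.05, hub_bias = 5,
                             target_tokens = 5000,
                             sentence_length = c(mean = 12, min = 2, max = 40),
                             seed = 1) {
  if (vocab_size < 10) stop_validation("vocab_size must be >= 10")
  if (zipf_exponent <= 0) stop_validation("zipf_exponent must be > 0")
  if (function_word_fraction < 0 || function_word_fraction >= 1)
    stop_validation("function_word_fraction must be in [0, 1)")
  if (hub_bias < 0) stop_validation("hub_bias must be >= 0")
  sl <- as.numeric(sentence_length)
  if (length(sl) != 3 || sl[2] < 2 || sl[3] < sl[2] || sl[1] < sl[2])
    stop_validation("sentence_length must be (mean, min, max) with min >= 2, max >= min, mean >= min")
  if (target_tokens < sl[2]) stop_validation("target_tokens must be >= min sentence length")
  structure(list(vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 function_word_fraction = function_word_fraction,
                 hub_bias = hub_bias,
                 target_tokens = as.integer(target_tokens),
                 sentence_length = c(mean = sl[1], min = sl[2], max = sl[3]),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample a Zipfian lexicon
#'
#' Word types `w0001..wV` with probabilities proportional to
#' `rank^-zipf_exponent`; the first
#' `ceiling(function_word_fraction * vocab_size)` ranks are flagged as
#' function words (high-frequency closed-class analogues).
#'
#' @param config A [generator_config()].
#' @return List with `form`, `prob` (normalized), `is_function`.
#' @export
sample_lexicon <- function(config) {
  v <- config$vocab_size
  prob <- seq_len(v)^(-config$zipf_exponent)
  prob <- prob / sum(prob)
  n_fun <- ceiling(config$function_word_fraction * v)
  width <- max(4, nchar(as.character(v)))
  list(form = sprintf(paste0("w%0", width, "d"), seq_len(v)),
       prob = prob,
       is_function = seq_len(v) <= n_fun)
}

## truncated geometric sentence length on [min, max] with the given mean
sample_sentence_length <- function(n, sl) {
  p <- 1 / (sl["mean"] - sl["min"] + 1)
  len <- sl["min"] + rgeom(n, p)
  while (any(bad <- len > sl["max"]))
    len[bad] <- sl["min"] + rgeom(sum(bad), p)
  as.integer(len)
}

#' Generate one sentence as a random recursive dependency tree
#'
#' Token forms are drawn independently from the lexicon.  Token 1 is the
#' root (relation `HED`, governor 0); each later token attaches to an
#' earlier token chosen with weight `1 + hub_bias * [governor token is a
#' function word]`, so positive bias funnels attachments through
#' function-word tokens.  Every sentence of n tokens carries exactly
#' n - 1 dependency edges.
#'
#' @param length Sentence length (>= 2).
#' @param lexicon A lexicon from [sample_lexicon()].
#' @param hub_bias Attachment bias (>= 0).
#' @param sentence_id Sentence id string.
#' @return A token data.frame in the treebank schema.
#' @export
generate_sentence <- function(length, lexicon, hub_bias = 0,
                              sentence_id = "s1") {
  stopifnot(length >= 2)
  ranks <- sample.int(length(lexicon$form), length, replace = TRUE,
                      prob = lexicon$prob)
  is_fun <- lexicon$is_function[ranks]
  gov <- integer(length)
  gov[1] <- 0L
  w <- 1 + hub_bias * is_fun
  for (i in seq_len(length)[-1]) {
    gov[i] <- if (i == 2) 1L else
      sample.int(i - 1L, 1L, prob = w[seq_len(i - 1L)])
  }
  data.frame(
    sentence_id = sentence_id,
    order = seq_len(length),
    form = lexicon$form[ranks],
    pos = ifelse(is_fun, "f", "c"),
    governor_order = gov,
    relation = ifelse(gov == 0L, "HED", "DEP"),
    is_punct = FALSE,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic treebank
#'
#' Emits sentences until `target_tokens` is reached (the last sentence may
#' overshoot by less than the maximum sentence length).  Deterministic
#' per seed.
#'
#' @param config A [generator_config()].
#' @param meta A [corpus_meta()] for the result.
#' @return A [treebank()].
#' @export
generate_treebank <- function(config, meta = corpus_meta()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    lex <- sample_lexicon(config)
    sl <- config$sentence_length
    sentences <- list()
    tokens_done <- 0L
    s <- 0L
    while (tokens_done < config$target_tokens) {
      s <- s + 1L
      len <- sample_sentence_length(1L, sl)
      sentences[[s]] <- generate_sentence(len, lex, config$hub_bias,
                                          sentence_id = sprintf("s%05d", s))
      tokens_done <- tokens_done + len
    }
    treebank(do.call(rbind, sentences), meta = meta, validate = FALSE)
  })
}

#' Default ten-corpus level plan
#'
#' Two modalities (written, oral) by four learner levels plus a native
#' reference.  Learner vocabulary grows 500, 800, 2000, 4000 with level
#' (the graded-curriculum progression); the native reference uses 6000.
#' The oral modality uses a steeper Zipf exponent (1.15 vs 1.0), encoding
#' the more repetitive vocabulary use of speech; all other knobs are
#' shared.  Per-corpus seeds are derived from the base seed.
#'
#' @param seed Base seed (default 1).
#' @param target_tokens Tokens per corpus (default 5000).
#' @return A `level_plan`: list of entries `(label, modality, level,
#'   config)`.
#' @export
default_level_plan <- function(seed = 1, target_tokens = 5000) {
  vocab <- c(500, 800, 2000, 4000, 6000)
  levels <- c("1", "2", "3", "4", "native")
  entries <- list()
  i <- 0L
  for (mod in c("written", "oral")) {
    zipf <- if (mod == "written") 1.0 else 1.15
    for (l in seq_along(levels)) {
      i <- i + 1L
      lab <- paste0(toupper(substr(mod, 1, 1)),
                    if (levels[l] == "native") "N" else levels[l])
      entries[[i]] <- list(
        label = lab, modality = mod, level = levels[l],
        config = generator_config(vocab_size = vocab[l],
                                  zipf_exponent = zipf,
                                  target_tokens = target_tokens,
                                  seed = seed * 100L + i))
    }
  }
  structure(entries, class = "level_plan")
}

#' Validate a level plan
#'
#' Labels must be unique and vocabulary sizes strictly increasing with
#' level within each modality.
#'
#' @param plan A `level_plan`.
#' @return `plan`, invisibly.
#' @export
validate_level_plan <- function(plan) {
  labs <- vapply(plan, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop_validation("duplicate corpus label(s): %s",
                    paste(unique(labs[duplicated(labs)]), collapse = ", "))
  for (mod in unique(vapply(plan, `[[`, "", "modality"))) {
    sel <- vapply(plan, function(e) e$modality == mod, TRUE)
    ent <- plan[sel]
    code <- level_code(vapply(ent, `[[`, "", "level"))
    vs <- vapply(ent, function(e) e$config$vocab_size, 1L)
    vs <- vs[order(code)]
    if (any(diff(vs) <= 0))
      stop_validation("vocabulary sizes must strictly increase with level (modality %s)",
                      mod)
  }
  invisible(plan)
}

#' Generate the full level series of treebanks
#'
#' @param plan A `level_plan` (default [default_level_plan()]).
#' @return Named list of treebanks, one per plan entry.
#' @export
generate_level_series <- function(plan = default_level_plan()) {
  validate_level_plan(plan)
  out <- lapply(plan, function(e)
    generate_treebank(e$config,
                      meta = corpus_meta(e$modality, e$level, e$label)))
  names(out) <- vapply(plan, `[[`, "", "label")
  out
}
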