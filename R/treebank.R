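## Core containers: Token rows, Sentence grouping, Treebank, CorpusMeta.
## A treebank is stored flat: one data.frame of token rows (grouped by
## sentence_id, file order preserved) plus corpus metadata.  Sentences are
## recovered by grouping on sentence_id.

#' Corpus metadata
#'
#' Describes one corpus in a study: its production modality, proficiency
#' level and a unique label (e.g. `"W3"` for written level 3, `"ON"` for
#' the oral native reference).
#'
#' @param modality `"written"` or `"oral"`.
#' @param level One of `1:4` (learner proficiency) or `"native"`.
#' @param label Free-form unique corpus label.
#' @return A `corpus_meta` list.
#' @export
corpus_meta <- function(modality = NA_character_, level = NA,
                        label = NA_character_) {
  if (!is.na(modality) && !modality %in% c("written", "oral"))
    stop_validation("modality must be 'written' or 'oral', got '%s'", modality)
  lev <- if (length(level) == 1 && !is.na(level)) as.character(level) else NA_character_
  if (!is.na(lev) && !lev %in% c("1", "2", "3", "4", "native"))
    stop_validation("level must be 1..4 or 'native', got '%s'", lev)
  structure(list(modality = modality, level = lev, label = label),
            class = "corpus_meta")
}

#' Construct a treebank from token rows
#'
#' @param tokens A data.frame with columns `sentence_id`, `order`, `form`,
#'   `pos`, `governor_order`, `relation`, `is_punct`.  Rows must be grouped
#'   by sentence and ordered by `order` within each sentence.
#' @param meta A [corpus_meta()] object.
#' @param validate Run [validate_treebank()] (default `TRUE`).
#' @param dialect Root-label convention for validation: `"paper"` enforces
#'   the HED/governor-0 equivalence, `"conllu"` downgrades foreign root
#'   labels to a warning.
#' @return A `treebank` object.
#' @export
treebank <- function(tokens, meta = corpus_meta(), validate = TRUE,
                     dialect = c("paper", "conllu")) {
  dialect <- match.arg(dialect)
  needed <- c("sentence_id", "order", "form", "pos", "governor_order",
              "relation", "is_punct")
  missing_cols <- setdiff(needed, names(tokens))
  if (length(missing_cols))
    stop_validation("token table lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
  tokens <- as.data.frame(tokens)[, needed]
  tokens$sentence_id <- as.character(tokens$sentence_id)
  tokens$order <- as.integer(tokens$order)
  tokens$form <- normalize_form(as.character(tokens$form))
  tokens$pos <- as.character(tokens$pos)
  tokens$governor_order <- as.integer(tokens$governor_order)
  tokens$relation <- as.character(tokens$relation)
  tokens$is_punct <- as.logical(tokens$is_punct)
  rownames(tokens) <- NULL
  tb <- structure(list(tokens = tokens, meta = meta), class = "treebank")
  if (validate) validate_treebank(tb, dialect = dialect)
  tb
}

#' @export
print.treebank <- function(x, ...) {
  cat(sprintf("<treebank> %s: %d sentences, %d tokens\n",
              x$meta$label %||% "?", n_sentences(x), n_tokens(x)))
  invisible(x)
}

#' Number of tokens in a treebank
#' @param tb A treebank.
#' @return Integer count.
#' @export
n_tokens <- function(tb) nrow(tb$tokens)

#' Number of sentences in a treebank
#' @param tb A treebank.
#' @return Integer count.
#' @export
n_sentences <- function(tb) length(unique(tb$tokens$sentence_id))

## Index of the first token of each sentence within the flat token table,
## in file order.  Used for O(1) governor lookups.
sentence_starts <- function(tb) {
  sid <- tb$tokens$sentence_id
  which(!duplicated(sid))
}

#' Validate treebank structural invariants
#'
#' Checks, per sentence: token orders are consecutive `1..n`; every
#' `governor_order` lies in `{0} U {1..n}`; no token governs itself; the
#' root relation is `HED` exactly on governor 0 (strict on the tabular
#' dialect, a warning for foreign CoNLL-U root labels).  Multi-root or
#' rootless sentences are tolerated with a warning: learner corpora can be
#' fragmentary and the annotation gives no repair rule worth guessing.
#'
#' @param tb A treebank.
#' @param dialect `"paper"` or `"conllu"` (root-label strictness).
#' @return `tb`, invisibly.
#' @export
validate_treebank <- function(tb, dialect = c("paper", "conllu")) {
  dialect <- match.arg(dialect)
  tk <- tb$tokens
  if (nrow(tk) == 0) stop_validation("no sentences")
  split_orders <- split(seq_len(nrow(tk)), tk$sentence_id)
  multi_root <- character(0)
  no_root <- character(0)
  for (sid in unique(tk$sentence_id)) {
    idx <- split_orders[[sid]]
    ord <- tk$order[idx]
    n <- length(ord)
    if (!identical(ord, seq_len(n)))
      stop_validation("sentence %s: token orders are not consecutive 1..%d",
                      sid, n)
    gov <- tk$governor_order[idx]
    if (any(gov < 0 | gov > n))
      stop_validation("sentence %s: governor_order out of range 0..%d",
                      sid, n)
    if (any(gov == ord))
      stop_validation("sentence %s: token governs itself", sid)
    root <- gov == 0
    rel <- tk$relation[idx]
    if (any(root & rel != "HED")) {
      if (dialect == "paper")
        stop_validation("sentence %s: governor 0 carries relation '%s', not HED",
                        sid, rel[root & rel != "HED"][1])
      else
        warn_syntnet("sentence %s: foreign root label '%s' (expected HED)",
                     sid, rel[root & rel != "HED"][1])
    }
    if (any(!root & rel == "HED"))
      stop_validation("sentence %s: HED relation on non-root token", sid)
    if (sum(root) > 1) multi_root <- c(multi_root, sid)
    if (sum(root) == 0) no_root <- c(no_root, sid)
  }
  if (length(multi_root))
    warn_syntnet("%d sentence(s) with multiple roots (e.g. %s)",
                 length(multi_root), multi_root[1])
  if (length(no_root))
    warn_syntnet("%d sentence(s) without a root (e.g. %s)",
                 length(no_root), no_root[1])
  invisible(tb)
}

#' Merge treebanks into one
#'
#' Concatenates sentences; sentence ids are prefixed with the source index
#' when duplicated across parts.  Metadata is taken from the first part.
#'
#' @param ... Treebanks.
#' @return A merged treebank.
#' @export
merge_treebanks <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  tabs <- lapply(seq_along(parts), function(i) {
    tk <- parts[[i]]$tokens
    tk$sentence_id <- paste0("p", i, ":", tk$sentence_id)
    tk
  })
  treebank(do.call(rbind, tabs), meta = parts[[1]]$meta, validate = FALSE)
}
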