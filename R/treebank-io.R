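## Readers and writers: the 7-column tabular annotation dialect, CoNLL-U,
## and Pajek .net export of built networks.  All paths may be plain or
## gzip-compressed (".gz").  Encoding is fixed to UTF-8; lines starting
## with '#' are comments.

#' Default POS tags treated as punctuation
#' @export
PUNCT_TAGS <- c("wp", "PU", "PUNCT")

#' Read the tabular dependency-annotation dialect
#'
#' The dialect has 7 columns per row, one row per token:
#' `sentence id, dependent order, dependent form, dependent POS,
#' governor order, governor form (placeholder on roots), dependency type`.
#' Rows are grouped by sentence id; sentence and token order follow the
#' file.  The governor-form column is redundant with the governor order;
#' it is cross-checked against the token found at that order and any
#' mismatch is reported as a warning, never silently repaired.
#'
#' @param path Input file (`.gz` allowed).
#' @param sep Field separator; default `"\t"`, `","` also common.
#' @param punct_tags POS tags flagged as punctuation.
#' @param meta A [corpus_meta()] for the resulting treebank.
#' @return A [treebank()].
#' @export
read_dependency_table <- function(path, sep = "\t", punct_tags = PUNCT_TAGS,
                                  meta = corpus_meta()) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_validation("no sentences in '%s'", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop_validation("line %d: expected 7 columns, found %d",
                    lineno[which(nf != 7L)[1]], nf[nf != 7L][1])
  m <- matrix(trimws(unlist(fields)), ncol = 7L, byrow = TRUE)
  ord <- suppressWarnings(as.integer(m[, 2]))
  gov <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(ord) || anyNA(gov))
    stop_validation("line %d: non-integer order column",
                    lineno[which(is.na(ord) | is.na(gov))[1]])
  tokens <- data.frame(
    sentence_id = m[, 1], order = ord, form = m[, 3], pos = m[, 4],
    governor_order = gov, relation = m[, 7],
    is_punct = m[, 4] %in% punct_tags,
    stringsAsFactors = FALSE
  )
  tb <- tryCatch(
    treebank(tokens, meta = meta, dialect = "paper"),
    syntnet_validation_error = function(e)
      stop_validation("%s: %s", path, conditionMessage(e))
  )
  check_governor_forms(tb, normalize_form(m[, 6]))
  tb
}

## Cross-check the redundant governor-form column; mismatches reported.
check_governor_forms <- function(tb, gov_form_col) {
  tk <- tb$tokens
  starts <- sentence_starts(tb)
  sid <- tk$sentence_id
  base <- starts[match(sid, sid[starts])]      # first row of own sentence
  gov_idx <- ifelse(tk$governor_order == 0, NA_integer_,
                    base + tk$governor_order - 1L)
  actual <- ifelse(is.na(gov_idx), NA_character_, tk$form[gov_idx])
  bad <- !is.na(actual) & actual != gov_form_col
  if (any(bad)) {
    i <- which(bad)[1]
    warn_syntnet(
      "%d governor-form mismatch(es): sentence %s token %d says '%s' but governor at order %d is '%s'",
      sum(bad), sid[i], tk$order[i], gov_form_col[i],
      tk$governor_order[i], actual[i])
  }
  invisible(sum(bad))
}

#' Write the tabular dependency-annotation dialect
#'
#' Inverse of [read_dependency_table()]; the round trip is lossless for
#' `(order, form, pos, governor_order, relation)`.
#'
#' @param tb A treebank.
#' @param path Output file (`.gz` allowed).
#' @param sep Field separator.
#' @export
write_dependency_table <- function(tb, path, sep = "\t") {
  tk <- tb$tokens
  starts <- sentence_starts(tb)
  base <- starts[match(tk$sentence_id, tk$sentence_id[starts])]
  gov_form <- rep("_", nrow(tk))
  has <- tk$governor_order > 0L
  gov_form[has] <- tk$form[(base + tk$governor_order - 1L)[has]]
  lines <- paste(tk$sentence_id, tk$order, tk$form, tk$pos,
                 tk$governor_order, gov_form, tk$relation, sep = sep)
  con <- open_output(path)
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Read a CoNLL-U treebank
#'
#' Standard 10-column CoNLL-U: multiword-token ranges (`1-2`) and empty
#' nodes (`1.1`) are skipped; `HEAD` maps to `governor_order`, `DEPREL` to
#' `relation`, `UPOS` to `pos`; `is_punct` is set from `punct_tags`
#' (UPOS `PUNCT` by default among them).  Foreign root labels (a `HEAD` of
#' 0 whose `DEPREL` is not `HED`) are tolerated with a warning.
#'
#' @param path Input file (`.gz` allowed).
#' @param punct_tags POS tags flagged as punctuation.
#' @param meta A [corpus_meta()].
#' @return A [treebank()].
#' @export
read_conllu <- function(path, punct_tags = PUNCT_TAGS, meta = corpus_meta()) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, encoding = "UTF-8")
  sent_id <- 0L
  in_sentence <- FALSE
  rows <- vector("list", length(lines))
  nr <- 0L
  for (li in seq_along(lines)) {
    line <- lines[li]
    if (grepl("^\\s*$", line)) { in_sentence <- FALSE; next }
    if (startsWith(line, "#")) next
    if (!in_sentence) { sent_id <- sent_id + 1L; in_sentence <- TRUE }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L)
      stop_validation("line %d: expected 10 CoNLL-U columns, found %d",
                      li, length(f))
    if (grepl("-", f[1], fixed = TRUE) || grepl(".", f[1], fixed = TRUE))
      next                              # multiword token / empty node
    id <- suppressWarnings(as.integer(f[1]))
    head_ <- suppressWarnings(as.integer(f[7]))
    if (is.na(id)) stop_validation("line %d: non-integer ID '%s'", li, f[1])
    if (is.na(head_)) stop_validation("line %d: non-integer HEAD '%s'", li, f[7])
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      sentence_id = sprintf("s%d", sent_id), order = id, form = f[2],
      pos = f[4], governor_order = head_, relation = f[8],
      is_punct = f[4] %in% punct_tags, stringsAsFactors = FALSE)
  }
  if (nr == 0L) stop_validation("no sentences in '%s'", path)
  treebank(do.call(rbind, rows[seq_len(nr)]), meta = meta,
           dialect = "conllu")
}

#' Write a CoNLL-U treebank
#'
#' @param tb A treebank.
#' @param path Output file (`.gz` allowed).
#' @export
write_conllu <- function(tb, path) {
  tk <- tb$tokens
  con <- open_output(path)
  on.exit(close(con))
  for (sid in unique(tk$sentence_id)) {
    s <- tk[tk$sentence_id == sid, ]
    writeLines(sprintf("# sent_id = %s", sid), con)
    writeLines(paste(s$order, s$form, "_", s$pos, "_", "_",
                     s$governor_order, s$relation, "_", "_", sep = "\t"),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export a syntactic network as a Pajek .net file
#'
#' Emits `*Vertices N` with 1-based quoted labels in the network's stable
#' vertex order, then `*Edges` lines `i j w` where `w` is the edge
#' multiplicity (number of dependency instances merged into the edge).
#'
#' @param network A `syntactic_network` (see [build_network()]).
#' @param path Output file (`.gz` allowed).
#' @export
write_pajek <- function(network, path) {
  if (network$N == 0) stop_validation("empty network")
  con <- open_output(path)
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", network$N), con)
  writeLines(sprintf('%d "%s"', seq_len(network$N), network$vertices), con)
  writeLines("*Edges", con)
  if (network$M > 0)
    writeLines(sprintf("%d %d %d", network$edges$i, network$edges$j,
                       network$edges$weight), con)
  invisible(path)
}

#' Read a Pajek .net file back into a syntactic network
#'
#' Companion to [write_pajek()] so pipeline stages can compose on files.
#'
#' @param path Input `.net` file (`.gz` allowed).
#' @return A `syntactic_network` (see [build_network()]).
#' @export
read_pajek <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, encoding = "UTF-8")
  vline <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  eline <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (!length(vline) || !length(eline))
    stop_validation("'%s' is not a Pajek .net file", path)
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vline[1]],
                      ignore.case = TRUE))
  vrows <- lines[(vline[1] + 1L):(eline[1] - 1L)]
  vrows <- vrows[nzchar(trimws(vrows))]
  labs <- sub('^\\s*\\d+\\s+"(.*)".*$', "\\1", vrows)
  ids <- as.integer(sub('^\\s*(\\d+)\\s.*$', "\\1", vrows))
  vertices <- character(n)
  vertices[ids] <- labs
  erows <- if (eline[1] < length(lines)) lines[(eline[1] + 1L):length(lines)] else character(0)
  erows <- erows[nzchar(trimws(erows))]
  if (length(erows)) {
    em <- do.call(rbind, strsplit(trimws(erows), "\\s+"))
    edges <- data.frame(i = as.integer(em[, 1]), j = as.integer(em[, 2]),
                        weight = as.integer(em[, 3]))
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), weight = integer(0))
  }
  new_syntactic_network(vertices, edges)
}
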