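# Lexical screening aid for item-criterion overlaps.
#
# The screen proposes verbatim and synonym candidates for human curation;
# concretisation (one text a more concrete example of the other) is a
# semantic judgement and is deliberately never emitted. The rubric consumes
# only curated overlap findings, never raw candidates.

# small fixed stop-word list; deliberately excludes negations and content
# adverbs ("rather", "not") that carry meaning in item texts
.stopwords <- c(
  "the", "a", "an", "and", "or", "of", "to", "in", "on", "at", "for",
  "with", "by", "from", "as", "that", "this", "these", "those", "it",
  "its", "is", "are", "was", "were", "be", "been", "being", "has",
  "have", "had", "do", "does", "did", "will", "would", "can", "could",
  "may", "might", "shall", "should", "than", "then", "there", "their",
  "they", "them", "he", "she", "his", "her", "when", "while", "which",
  "who", "whom", "into", "onto", "over", "under", "such", "other", "more"
)

# light suffix stripping with minimum-stem-length guards, so short
# participles survive ("fixed" stays "fixed") while plurals and long
# inflections are normalized ("tends" -> "tend", "learning" -> "learn")
light_stem <- function(tok) {
  vapply(tok, function(w) {
    n <- nchar(w)
    if (n > 6L && endsWith(w, "ing")) return(substr(w, 1L, n - 3L))
    if (n > 5L && endsWith(w, "ed")) return(substr(w, 1L, n - 2L))
    if (n > 4L && (endsWith(w, "ses") || endsWith(w, "xes") ||
                   endsWith(w, "zes") || endsWith(w, "ches") ||
                   endsWith(w, "shes"))) {
      return(substr(w, 1L, n - 2L))
    }
    if (n >= 3L && endsWith(w, "s") && !endsWith(w, "ss")) {
      return(substr(w, 1L, n - 1L))
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize free text into content tokens
#'
#' Case-folds, strips punctuation, drops stop words and applies light,
#' deterministic suffix stemming (plural "s"/"es"; "ing"/"ed" only when a
#' long stem remains). No dictionaries or language models are involved, so
#' the result is reproducible across platforms.
#'
#' @param s a character string.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' normalize_text("Fixed facial expression(s)")
#' normalize_text("Rather solitary, tends to play alone")
normalize_text <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- tolower(s)
  s <- gsub("[^a-z0-9]+", " ", s)
  tok <- strsplit(trimws(s), " +")[[1]]
  tok <- tok[nchar(tok) > 1L & !tok %in% .stopwords]
  light_stem(tok)
}

#' The shipped synonym lexicon
#'
#' Reads a plain-text lexicon of synonym pairs (one pair per line, two
#' tokens separated by whitespace; `#` starts a comment). Pairs are
#' symmetric; no transitive closure is applied. The shipped default seeds
#' the rubric's canonical example pair (hyperactive/overactive) plus a few
#' common mental-health synonym pairs; it is meant to be copied and edited
#' per review.
#'
#' @param path path to a lexicon file; default: the shipped lexicon.
#' @return A two-column character matrix of stemmed token pairs.
#' @export
read_lexicon <- function(path = system.file("extdata", "synonym_lexicon.txt",
                                            package = "robndd")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("lexicon lines must hold exactly two tokens (line %d)",
                 which(bad)[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  matrix(light_stem(tolower(m)), ncol = 2L,
         dimnames = list(NULL, c("a", "b")))
}

#' Screen one item-criterion pair for lexical overlap
#'
#' Emits a `"verbatim"` candidate when the Jaccard similarity of the
#' normalized content-token sets reaches `verbatim_cutoff`; failing that, a
#' `"synonym"` candidate when at least one lexicon pair bridges the two
#' texts. Confidence is the Jaccard similarity after merging bridged token
#' pairs, so it is monotone in the token-overlap fraction. Returns `NULL`
#' when neither rule fires: such pairs (including true concretisations) are
#' left to human review.
#'
#' The function is symmetric in its two texts.
#'
#' @param item_text instrument item.
#' @param criterion_text diagnostic criterion.
#' @param lexicon a synonym lexicon matrix from [read_lexicon()].
#' @param verbatim_cutoff Jaccard cut-off for a verbatim call (default 0.5;
#'   the screen favours recall, humans confirm).
#' @return A list of class `overlap_candidate` with `item_text`,
#'   `criterion_text`, `match_code`, `matched_tokens` and `confidence`, or
#'   `NULL`.
#' @export
#' @examples
#' screen_pair("hyperactive", "overactive")
screen_pair <- function(item_text, criterion_text,
                        lexicon = read_lexicon(),
                        verbatim_cutoff = 0.5) {
  a <- unique(normalize_text(item_text))
  b <- unique(normalize_text(criterion_text))
  if (length(a) == 0L || length(b) == 0L) {
    # no content tokens survive (e.g. stop-word-only texts): fall back to
    # direct case-folded comparison so identical text is never silent
    fold <- function(s) trimws(gsub("[^a-z0-9]+", " ", tolower(s)))
    if (nzchar(fold(item_text)) &&
        identical(fold(item_text), fold(criterion_text))) {
      return(structure(list(
        item_text = item_text, criterion_text = criterion_text,
        match_code = "verbatim", matched_tokens = fold(item_text),
        confidence = 1
      ), class = "overlap_candidate"))
    }
    return(NULL)
  }
  shared <- intersect(a, b)
  union_n <- length(union(a, b))
  jac <- length(shared) / union_n
  if (jac >= verbatim_cutoff) {
    return(structure(list(
      item_text = item_text, criterion_text = criterion_text,
      match_code = "verbatim", matched_tokens = sort(shared),
      confidence = jac
    ), class = "overlap_candidate"))
  }
  # symmetric lexicon bridging on the non-shared tokens
  ra <- setdiff(a, b); rb <- setdiff(b, a)
  bridge_a <- character(0); bridge_b <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    x <- lexicon[i, 1L]; y <- lexicon[i, 2L]
    if ((x %in% ra && y %in% rb)) { bridge_a <- c(bridge_a, x); bridge_b <- c(bridge_b, y) }
    if ((y %in% ra && x %in% rb)) { bridge_a <- c(bridge_a, y); bridge_b <- c(bridge_b, x) }
  }
  n_bridge <- length(unique(bridge_a))
  if (n_bridge > 0L) {
    conf <- min(1, (length(shared) + n_bridge) / (union_n - n_bridge))
    return(structure(list(
      item_text = item_text, criterion_text = criterion_text,
      match_code = "synonym",
      matched_tokens = sort(unique(c(shared, bridge_a, bridge_b))),
      confidence = conf
    ), class = "overlap_candidate"))
  }
  NULL
}

#' @export
print.overlap_candidate <- function(x, ...) {
  cat(sprintf("<overlap_candidate> %s (confidence %.2f)\n", x$match_code,
              x$confidence))
  cat(sprintf("  item:      %s\n  criterion: %s\n  tokens:    %s\n",
              x$item_text, x$criterion_text,
              paste(x$matched_tokens, collapse = ", ")))
  invisible(x)
}

#' Screen all item-criterion pairs
#'
#' Crosses every instrument item with every diagnostic criterion and
#' collects the candidates proposed by [screen_pair()]. Output is advisory:
#' it mirrors the overlap-table columns and is meant for human curation
#' into [overlap_finding()] records, never for direct consumption by the
#' rubric.
#'
#' @param items character vector of instrument items.
#' @param criteria character vector of diagnostic criteria.
#' @inheritParams screen_pair
#' @return A data.frame with columns `item`, `criterion`, `match_code`,
#'   `matched_tokens` (";"-separated) and `confidence`; zero rows when
#'   nothing fires.
#' @export
screen_overlaps <- function(items, criteria, lexicon = read_lexicon(),
                            verbatim_cutoff = 0.5) {
  rows <- list()
  for (it in items) {
    for (cr in criteria) {
      cand <- screen_pair(it, cr, lexicon, verbatim_cutoff)
      if (!is.null(cand)) {
        rows[[length(rows) + 1L]] <- data.frame(
          item = it, criterion = cr, match_code = cand$match_code,
          matched_tokens = paste(cand$matched_tokens, collapse = ";"),
          confidence = cand$confidence, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(item = character(0), criterion = character(0),
                      match_code = character(0),
                      matched_tokens = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
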