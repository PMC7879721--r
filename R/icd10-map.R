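#' Load an ICD-10 symptom-descriptor lexicon
#'
#' The packaged default maps twelve symptom buckets — acute stress (F43.0),
#' PTSD (F43.1, sharing the acute-stress phenomenology), paranoia (F22),
#' grief (Z63.4), insomnia (G47.00), panic (F41.0), agoraphobia (F40.00),
#' nonsuicidal self-injury (Z91.5), obsession-compulsion (F42.9),
#' hypochondriasis (F45.21), anxiety (F41.9), and a COVID-19-specific
#' bucket — to short symptom-descriptor phrases. The file is editable JSON
#' (`{code: {label, phrases: [...]}}`); it is a compact symptom inventory,
#' not an ingestion of the full licensed ICD-10 text.
#'
#' @param path Path to a JSON lexicon; `NULL` loads the packaged default.
#' @return Named list of `list(label, phrases)`, class `"symptom_lexicon"`.
#' @export
symptom_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "icd10_symptoms.json",
                                package = "textpheno", mustWork = TRUE)
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(lex)) stop("configuration error: empty symptom lexicon")
  if (anyDuplicated(names(lex))) stop("ICD-10 codes must be unique")
  bad <- vapply(lex, function(e) is.null(e$phrases) || !length(e$phrases),
                logical(1))
  if (any(bad)) stop("every code needs at least one descriptor phrase")
  structure(lex, class = "symptom_lexicon")
}

# Function words excluded from descriptor content tokens, so that matches
# are carried by symptom vocabulary rather than by "the"/"about"/"of".
descriptor_stopwords <- function() {
  c("the", "a", "an", "and", "or", "of", "to", "in", "on", "at", "by",
    "for", "with", "without", "about", "as", "is", "are", "be", "being",
    "been", "that", "this", "it", "its", "one", "ones", "oneself", "do",
    "does", "did", "who", "whether", "which", "should", "might", "may",
    "not", "no", "if", "even", "was", "were", "you", "your", "over",
    "again", "too", "much", "own")
}

# Prefix-stem match between two word tokens: one must be a prefix of the
# other, and the shared stem must be at least 3 characters.
stem_match <- function(a, b) {
  (nchar(a) >= 3 & nchar(b) >= 3) & (startsWith(a, b) | startsWith(b, a))
}

#' Match terms against ICD-10 symptom descriptors
#'
#' A term supports a code iff any of its word tokens prefix-stem-matches
#' any content token (stop words removed) of any descriptor phrase of that
#' code. A term may support several codes; terms supporting none are
#' listed as unmatched for downstream human inspection.
#'
#' @param terms Character vector of terms (n-grams allowed).
#' @param lexicon A [symptom_lexicon()].
#' @return Object of class `"symptom_match_report"`: `counts` (data.frame
#'   `code`, `label`, `n`), `by_code` (named list of supporting terms),
#'   `best_descriptor` (data.frame `term`, `code`, `descriptor`: the
#'   best-matching phrase per matched term), `unmatched` (character),
#'   `terms` (the input).
#' @export
match_symptoms <- function(terms, lexicon = symptom_lexicon()) {
  if (!inherits(lexicon, "symptom_lexicon")) stop("need a symptom_lexicon")
  terms <- unique(as.character(terms))
  codes <- names(lexicon)
  stops <- descriptor_stopwords()

  phrase_tokens <- lapply(lexicon, function(entry) {
    lapply(entry$phrases, function(ph) {
      tk <- tokenize_words(ph)
      tk[!(tk %in% stops) & nchar(tk) >= 3]
    })
  })

  by_code <- stats::setNames(vector("list", length(codes)), codes)
  for (code in codes) by_code[[code]] <- character(0)
  best <- list()
  unmatched <- character(0)

  for (term in terms) {
    toks <- tokenize_words(term)
    best_score <- 0
    best_code <- NA_character_
    best_phrase <- NA_character_
    hit_any <- FALSE
    if (length(toks)) {
      for (code in codes) {
        phr <- lexicon[[code]]$phrases
        ptk <- phrase_tokens[[code]]
        code_hit <- FALSE
        for (j in seq_along(ptk)) {
          ct <- ptk[[j]]
          if (!length(ct)) next
          score <- sum(vapply(toks, function(t) any(stem_match(t, ct)),
                              logical(1)))
          if (score > 0) {
            code_hit <- TRUE
            if (score > best_score) {
              best_score <- score
              best_code <- code
              best_phrase <- phr[j]
            }
          }
        }
        if (code_hit) {
          by_code[[code]] <- c(by_code[[code]], term)
          hit_any <- TRUE
        }
      }
    }
    if (hit_any) {
      best[[term]] <- c(best_code, best_phrase)
    } else {
      unmatched <- c(unmatched, term)
    }
  }

  best_df <- if (length(best)) {
    data.frame(term = names(best),
               code = vapply(best, `[`, character(1), 1),
               descriptor = vapply(best, `[`, character(1), 2),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(term = character(0), code = character(0),
               descriptor = character(0), stringsAsFactors = FALSE)
  }
  counts <- data.frame(
    code = codes,
    label = vapply(lexicon, function(e) e$label %||% "", character(1)),
    n = vapply(by_code, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(counts = counts, by_code = by_code,
                 best_descriptor = best_df, unmatched = unmatched,
                 terms = terms),
            class = "symptom_match_report")
}

#' @export
print.symptom_match_report <- function(x, ...) {
  cat(sprintf("ICD-10 symptom matches over %d terms (%d unmatched)\n",
              length(x$terms), length(x$unmatched)))
  hit <- x$counts[x$counts$n > 0, , drop = FALSE]
  if (nrow(hit)) {
    for (i in seq_len(nrow(hit)))
      cat(sprintf("  %-8s %-32s %d term(s)\n",
                  hit$code[i], hit$label[i], hit$n[i]))
  } else {
    cat("  no code supported by any term\n")
  }
  invisible(x)
}
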