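#' Load a topical category lexicon
#'
#' The packaged default is a transparent cue-word lexicon covering eleven
#' topical categories (confusion/negative emotions, health/medical
#' emergencies, work/business/economic, technology/internet,
#' cleaning/hygiene, government/leadership, traveling/shopping,
#' party/celebration, positive emotion/love, friends/children, optimism).
#' Cues are lowercase stems matched by prefix, so the cue "lone" covers
#' "lonely" and "loneliness". The file is plain JSON
#' (`{category: [cues...]}`) and can be edited or replaced wholesale; an
#' embedding-derived categorizer can be swapped in behind the same
#' single-category interface.
#'
#' @param path Path to a JSON lexicon; `NULL` loads the packaged default.
#' @return Named list of character cue vectors, class `"category_lexicon"`.
#' @export
category_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "category_lexicon.json",
                                package = "textpheno", mustWork = TRUE)
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(lex)) stop("configuration error: empty category lexicon")
  if (anyDuplicated(names(lex))) stop("category names must be unique")
  lex <- lapply(lex, function(v) tolower(as.character(v)))
  if (any(lengths(lex) == 0)) stop("every category needs at least one cue")
  structure(lex, class = "category_lexicon")
}

#' Assign each term to a single topical category
#'
#' Each category is scored as the number of its cue stems that
#' prefix-match any word token of the term; the term goes to the single
#' highest-scoring category (ties broken by lexicographically smallest
#' category name), or to unassigned (`NA`) when no cue matches at all.
#'
#' @param terms Character vector of terms (n-grams allowed; every token is
#'   considered).
#' @param lexicon A [category_lexicon()].
#' @return data.frame with `term` and `category` (`NA` = unassigned), in
#'   input order.
#' @export
assign_categories <- function(terms, lexicon = category_lexicon()) {
  if (!inherits(lexicon, "category_lexicon")) stop("need a category_lexicon")
  if (!length(lexicon)) stop("configuration error: empty category lexicon")
  cats <- sort(names(lexicon))
  cat_of <- vapply(as.character(terms), function(term) {
    toks <- tokenize_words(term)
    if (!length(toks)) return(NA_character_)
    scores <- vapply(cats, function(cn) {
      sum(vapply(lexicon[[cn]],
                 function(cue) any(startsWith(toks, cue)), logical(1)))
    }, numeric(1))
    if (max(scores) == 0) NA_character_ else cats[which.max(scores)]
  }, character(1))
  data.frame(term = as.character(terms), category = unname(cat_of),
             stringsAsFactors = FALSE)
}

#' Category percentage breakdown of a term set
#'
#' Counts per category (plus an explicit `unassigned` bucket) and the
#' percentage of the full input term set each represents, rounded half
#' away from zero to the nearest integer — the convention for reporting
#' topical breakdowns of a selected vocabulary.
#'
#' @param assignments Output of [assign_categories()].
#' @return data.frame of class `"category_breakdown"` with `category`,
#'   `n`, `percentage`; counts sum to the input size.
#' @export
category_percentages <- function(assignments) {
  if (nrow(assignments) == 0) stop("empty assignment set: no breakdown")
  cat <- assignments$category
  cat[is.na(cat)] <- "unassigned"
  lev <- c(sort(unique(cat[cat != "unassigned"])),
           if (any(cat == "unassigned")) "unassigned")
  n <- as.integer(table(factor(cat, levels = lev)))
  out <- data.frame(category = lev, n = n,
                    percentage = percent(n, nrow(assignments), digits = 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("category_breakdown", "data.frame")
  out
}
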