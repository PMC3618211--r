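#' Interaction-keyword lexicon
#'
#' The rule engine recognizes an interaction trigger only when a token is a
#' morphological form of one of 67 curated keyword lemmas, each assigned to
#' one of five interaction categories (Activation, Deactivation, Creating
#' bond, Breaking bond, Signaling). The lexicon ships as a TSV data file and
#' can be replaced by a user-supplied file with the same two-column layout.
#'
#' @param path Path to a TSV file with columns \code{lemma} and
#'   \code{category}. Defaults to the packaged keyword list.
#' @return An object of class \code{ppi_lexicon}: a list with
#'   \describe{
#'     \item{entries}{named character vector, lemma -> category}
#'     \item{derived_forms}{named character vector, surface form -> lemma}
#'   }
#' @examples
#' lex <- load_default_lexicon()
#' length(lex$entries)           # 67
#' match_keyword("binding", lexicon = lex)$lemma   # "bind"
#' @export
load_default_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "relation_keywords.tsv", package = "ppirules")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lemma", "category") %in% names(tab)))
  entries <- stats::setNames(tab$category, tolower(tab$lemma))
  if (anyDuplicated(names(entries)) > 0L) {
    stop("duplicate lemma in lexicon file: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  }
  structure(
    list(entries = entries, derived_forms = build_derived_forms(names(entries))),
    class = "ppi_lexicon"
  )
}

#' @export
print.ppi_lexicon <- function(x, ...) {
  cat("<ppi_lexicon> ", length(x$entries), " lemmas, ",
      length(unique(x$entries)), " categories, ",
      length(x$derived_forms), " surface forms\n", sep = "")
  invisible(x)
}

# Deterministic morphological expansion of a keyword lemma: inflected verb
# forms (-s/-es, -ed, -ing) and the nominalizations the rules rely on
# (-ion/-ation/-ization/-ing nouns, plus plurals). Irregulars live in an
# explicit exception table so every mapping is auditable.
#
# "bound" is a lexicon lemma in its own right (distinct from "bind"), so the
# surface form "bound" maps to the lemma "bound", never to "bind"; "bind"
# keeps its true irregular past through the exception table only where it
# cannot collide.
nominalization_exceptions <- c(
  form       = "formation",
  reduce     = "reduction",
  repress    = "repression",
  suppress   = "suppression",
  recognize  = "recognition",
  participate = "participation",
  respond    = "response"
)

build_derived_forms <- function(lemmas) {
  out <- character(0)
  add <- function(forms, lemma) {
    forms <- setdiff(unique(tolower(forms)), names(out))
    stats::setNames(rep(lemma, length(forms)), forms)
  }
  for (lemma in lemmas) {
    forms <- lemma
    # 3rd person / plural
    if (grepl("(s|x|z|ch|sh)$", lemma)) {
      forms <- c(forms, paste0(lemma, "es"))
    } else if (grepl("[^aeiou]y$", lemma)) {
      forms <- c(forms, sub("y$", "ies", lemma))
    } else {
      forms <- c(forms, paste0(lemma, "s"))
    }
    # past tense / participle (regular only; irregulars via exceptions)
    if (grepl("e$", lemma)) {
      forms <- c(forms, paste0(lemma, "d"))
    } else if (grepl("[^aeiou]y$", lemma)) {
      forms <- c(forms, sub("y$", "ied", lemma))
    } else if (!lemma %in% c("bind", "bound")) {
      forms <- c(forms, paste0(lemma, "ed"))
    }
    # -ing form (gerund doubles as the nominal form for e.g. "binding")
    ing <- if (grepl("[^e]e$", lemma)) sub("e$", "ing", lemma) else paste0(lemma, "ing")
    forms <- c(forms, ing, paste0(ing, "s"))
    # nominalizations
    nom <- if (lemma %in% names(nominalization_exceptions)) {
      nominalization_exceptions[[lemma]]
    } else if (grepl("ate$", lemma)) {
      sub("e$", "ion", lemma)
    } else if (grepl("ize$", lemma)) {
      sub("e$", "ation", lemma)
    } else if (grepl("(t|ss)$", lemma)) {
      paste0(lemma, "ion")
    } else {
      NA_character_
    }
    if (!is.na(nom)) forms <- c(forms, nom, paste0(nom, "s"))
    out <- c(out, add(forms, lemma))
  }
  out
}

#' Match a token against the interaction lexicon
#'
#' A token matches when its lemma is a lexicon lemma, or when its (case-folded)
#' surface form is one of the deterministically derived inflected or
#' nominalized forms of a lexicon lemma.
#'
#' @param text Token surface string.
#' @param lemma Optional lemma supplied by the parser; checked first.
#' @param lexicon A \code{ppi_lexicon}.
#' @return \code{NULL} if no match; otherwise a list with \code{lemma} (the
#'   base lexicon lemma) and \code{category}.
#' @export
match_keyword <- function(text, lemma = NULL, lexicon = load_default_lexicon()) {
  if (!is.null(lemma) && !is.na(lemma)) {
    lem <- tolower(lemma)
    if (lem %in% names(lexicon$entries)) {
      return(list(lemma = lem, category = unname(lexicon$entries[[lem]])))
    }
  }
  surf <- tolower(text)
  if (surf %in% names(lexicon$derived_forms)) {
    base <- unname(lexicon$derived_forms[[surf]])
    return(list(lemma = base, category = unname(lexicon$entries[[base]])))
  }
  NULL
}
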