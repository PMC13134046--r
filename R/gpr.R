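## Gene-protein-reaction (GPR) boolean rules.
##
## A GPR is stored as a small expression tree: a leaf is a gene id
## (character scalar), an inner node is list(op = "and"|"or", args = list).
## NULL means "no gene association" (spontaneous or orphan reaction).

#' Parse a GPR rule string
#'
#' Parses boolean gene-association rules such as \code{"(g1 and g2) or g3"}
#' into an expression tree.  \code{and}/\code{or} are case-insensitive and
#' the symbolic forms \code{&}, \code{&&}, \code{|}, \code{||} are accepted.
#' \code{and} binds tighter than \code{or}.  An empty or \code{NA} string
#' yields \code{NULL} (no gene association).
#'
#' @param text character scalar with the rule.
#' @return A GPR expression tree (\code{NULL}, a gene id, or a nested list
#'   with elements \code{op} and \code{args}).
#' @examples
#' gpr <- parseGPR("(g1 and g2) or g3")
#' evaluateGPR(gpr, knockedOut = "g1")
#' @export
parseGPR <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  txt <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(txt, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  norm <- function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "and"
    else if (tl %in% c("or", "|", "||")) "or"
    else t
  }
  toks <- vapply(toks, norm, "", USE.NAMES = FALSE)
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos] }
  parsePrimary <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error in '", text, "': unexpected end")
    if (t == "(") {
      advance()
      e <- parseOr()
      if (!identical(peek(), ")"))
        stop("GPR parse error in '", text, "': missing ')'")
      advance()
      e
    } else if (t %in% c(")", "and", "or")) {
      stop("GPR parse error in '", text, "': unexpected '", t, "'")
    } else {
      advance()
    }
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (identical(peek(), "and")) {
      advance()
      args <- c(args, list(parsePrimary()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (identical(peek(), "or")) {
      advance()
      args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  out <- parseOr()
  if (pos != length(toks))
    stop("GPR parse error in '", text, "': trailing tokens")
  out
}

.gprIsLeaf <- function(gpr) is.character(gpr)

#' Deparse a GPR expression tree back to rule text
#'
#' @param gpr a GPR expression tree as returned by [parseGPR()].
#' @return character scalar; `""` for an empty (NULL) GPR.
#' @export
gprToString <- function(gpr) {
  if (is.null(gpr)) return("")
  if (.gprIsLeaf(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- gprToString(a)
    if (!.gprIsLeaf(a) && !is.null(a)) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' Genes referenced by a GPR
#'
#' @param gpr a GPR expression tree.
#' @return character vector of unique gene ids (empty for NULL GPR).
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (.gprIsLeaf(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gprGenes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Evaluates the boolean rule with the knocked-out genes set to FALSE and
#' all other genes TRUE.  An empty GPR always evaluates TRUE (the reaction
#' needs no gene product).
#'
#' @param gpr GPR expression tree.
#' @param knockedOut character vector of knocked-out gene ids.
#' @param genes optional character vector of known model genes; leaves not
#'   in this set trigger a warning and are treated as present.
#' @return logical scalar.
#' @export
evaluateGPR <- function(gpr, knockedOut = character(0), genes = NULL) {
  if (!is.null(genes)) {
    unknown <- setdiff(gprGenes(gpr), genes)
    if (length(unknown))
      warning("GPR references genes absent from the model (treated as present): ",
              paste(unknown, collapse = ", "))
  }
  .evalGPR(gpr, knockedOut)
}

.evalGPR <- function(gpr, knockedOut) {
  if (is.null(gpr)) return(TRUE)
  if (.gprIsLeaf(gpr)) return(!(gpr %in% knockedOut))
  vals <- vapply(gpr$args, .evalGPR, NA, knockedOut = knockedOut)
  if (gpr$op == "and") all(vals) else any(vals)
}

## Expression score of a GPR: AND -> min of children, OR -> max.
## Genes missing from `scores` contribute 0.  Returns NA for empty GPR.
.gprScore <- function(gpr, scores) {
  if (is.null(gpr)) return(NA_real_)
  if (.gprIsLeaf(gpr)) {
    if (gpr %in% names(scores)) return(unname(scores[gpr]))
    return(0)
  }
  vals <- vapply(gpr$args, .gprScore, 0, scores = scores)
  if (gpr$op == "and") min(vals) else max(vals)
}
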