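#' @keywords internal
MORPHOLOGY_LABELS <- c("m", "sm", "st", "t", "a")

#' Construct a karyotype formula
#'
#' A karyotype formula gives the number of chromosomes of each morphology
#' class in the complement, e.g. \code{"12 m + 6 sm + 4 a"}. The five
#' recognised labels are \code{m} (metacentric), \code{sm} (submetacentric),
#' \code{st} (subtelocentric), \code{t} (telocentric) and \code{a}
#' (acrocentric; used by some sources for near-terminal centromeres and
#' treated as one-armed, like \code{t}).
#'
#' @param m,sm,st,t,a Non-negative integer chromosome counts per class.
#' @return An object of class \code{karyotype_formula}: a named integer
#'   vector with one element per morphology label.
#' @examples
#' karyotype_formula(m = 12, sm = 6, a = 4)
#' @export
karyotype_formula <- function(m = 0L, sm = 0L, st = 0L, t = 0L, a = 0L) {
  counts <- c(m = m, sm = sm, st = st, t = t, a = a)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("karyotype formula counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(round(counts)), names = MORPHOLOGY_LABELS,
            class = "karyotype_formula")
}

#' Parse a karyotype formula string
#'
#' Parses strings such as \code{"28 m + 14 sm"} or \code{"12 m + 6 sm + 4 a"}
#' into counts per morphology class. Terms are \code{"<count> <label>"}
#' joined by \code{"+"}; whitespace is free (\code{"10 m +16 sm"} parses).
#' Duplicate labels are summed.
#'
#' @param text A single formula string.
#' @return A \code{karyotype_formula}.
#' @seealso [format_formula()] for the canonical inverse.
#' @examples
#' parse_formula("28 m + 14 sm")
#' parse_formula("12 m + 6 sm + 4 a")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  terms <- strsplit(text, "+", fixed = TRUE)[[1L]]
  terms <- trimws(terms)
  if (any(!nzchar(terms))) {
    stop("empty term in karyotype formula: '", text, "'", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(MORPHOLOGY_LABELS)), MORPHOLOGY_LABELS)
  for (term in terms) {
    parts <- regmatches(term, regexec("^([0-9]+)\\s*([A-Za-z]+)$", term))[[1L]]
    if (length(parts) != 3L) {
      stop("cannot parse karyotype formula term: '", term, "'", call. = FALSE)
    }
    label <- parts[3L]
    if (!label %in% MORPHOLOGY_LABELS) {
      stop("unknown morphology label '", label, "' in term '", term, "'",
           call. = FALSE)
    }
    counts[label] <- counts[label] + as.integer(parts[2L])
  }
  do.call(karyotype_formula, as.list(counts))
}

#' Format a karyotype formula canonically
#'
#' The canonical form lists positive counts in the fixed label order
#' m, sm, st, t, a, joined by \code{" + "}, so that
#' \code{parse_formula(format_formula(f))} recovers \code{f}.
#'
#' @param formula A \code{karyotype_formula} (or named counts coercible to one).
#' @return A single string.
#' @examples
#' format_formula(karyotype_formula(m = 24, sm = 4))
#' @export
format_formula <- function(formula) {
  formula <- as_karyotype_formula(formula)
  pos <- formula[formula > 0L]
  if (length(pos) == 0L) return("")
  paste(paste(pos, names(pos)), collapse = " + ")
}

#' @export
print.karyotype_formula <- function(x, ...) {
  cat("<karyotype formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Coerce named counts to a karyotype formula
#'
#' @param x A \code{karyotype_formula}, a named numeric vector, or a named
#'   list with names among m, sm, st, t, a.
#' @return A \code{karyotype_formula}.
#' @export
as_karyotype_formula <- function(x) {
  if (inherits(x, "karyotype_formula")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !all(names(x) %in% MORPHOLOGY_LABELS)) {
    stop("names must be among: ", paste(MORPHOLOGY_LABELS, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(integer(length(MORPHOLOGY_LABELS)), MORPHOLOGY_LABELS)
  full[names(x)] <- as.integer(x)
  do.call(karyotype_formula, as.list(full))
}

#' Fundamental number (total arm count) of a karyotype formula
#'
#' Biarmed chromosomes (m, sm, st) contribute two arms each; one-armed
#' chromosomes (t, a) contribute one.
#'
#' @param formula A \code{karyotype_formula} or anything
#'   [as_karyotype_formula()] accepts.
#' @return Integer arm count.
#' @examples
#' fundamental_number(parse_formula("30 m + 14 sm + 6 st")) # 100
#' fundamental_number(parse_formula("12 m + 6 sm + 4 a"))   # 40
#' @export
fundamental_number <- function(formula) {
  f <- as_karyotype_formula(formula)
  unname(2L * (f[["m"]] + f[["sm"]] + f[["st"]]) + f[["t"]] + f[["a"]])
}
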