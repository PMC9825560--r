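# Chemistry backend: thin wrappers around OpenBabel (ChemmineOB).
# Everything in the package that parses, canonicalizes, measures or
# substructure-counts a molecule funnels through here.

.ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

.ob_props <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::prop_OB(.ob_mol(smiles)))
  if (!is.data.frame(out) || nrow(out) != 1L)
    stop("chemistry backend failed to parse SMILES: ", smiles, call. = FALSE)
  out
}

# OpenBabel silently "repairs" many malformed SMILES (unbalanced parentheses
# collapse to a fragment), so user-facing input gets a syntax pre-check that
# rejects what a strict parser would reject.
check_smiles_syntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    return("SMILES must be a single non-empty string")
  if (grepl("[[:space:]]", smiles))
    return("SMILES must not contain whitespace")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_bracket <- FALSE
  ring <- integer(0)
  i <- 1L
  n <- length(chars)
  allowed <- c(LETTERS, letters, as.character(0:9),
               "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\",
               "@", "%", "*", ".", ":")
  while (i <= n) {
    ch <- chars[i]
    if (!ch %in% allowed) return(paste0("illegal character '", ch, "'"))
    if (in_bracket) {
      if (ch == "[") return("nested '[' in atom bracket")
      if (ch == "]") in_bracket <- FALSE
    } else if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return("unmatched ']'")
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return("unmatched ')'")
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        return("'%' ring closure must be followed by two digits")
      num <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ring <- if (num %in% ring) setdiff(ring, num) else c(ring, num)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      num <- as.integer(ch)
      ring <- if (num %in% ring) setdiff(ring, num) else c(ring, num)
    }
    i <- i + 1L
  }
  if (in_bracket) return("unclosed '['")
  if (depth != 0L) return("unclosed '('")
  if (length(ring) > 0L)
    return(paste0("unpaired ring-closure digit(s): ",
                  paste(ring, collapse = ", ")))
  NULL
}

#' Canonicalize a SMILES string
#'
#' Returns the backend's canonical isomeric SMILES. All molecular equality
#' comparisons in the package are string equality of this form.
#'
#' @param smiles A single SMILES string.
#' @param strict Run the syntax pre-check before parsing (recommended for
#'   user-supplied input; internal callers that generated the string
#'   themselves may skip it).
#' @return A canonical SMILES string.
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  if (strict) {
    msg <- check_smiles_syntax(smiles)
    if (!is.null(msg)) stop("invalid SMILES '", smiles, "': ", msg, call. = FALSE)
  }
  p <- .ob_props(smiles)
  cs <- sub("[[:space:]]+$", "", p$cansmi[1])
  if (!nzchar(cs)) stop("chemistry backend returned an empty structure for: ",
                        smiles, call. = FALSE)
  cs
}

#' Molecular formula of a SMILES string
#'
#' @inheritParams canonical_smiles
#' @return A formula string in Hill order, e.g. `"C6H12O3"`.
#' @export
molecular_formula <- function(smiles, strict = TRUE) {
  if (strict) {
    msg <- check_smiles_syntax(smiles)
    if (!is.null(msg)) stop("invalid SMILES '", smiles, "': ", msg, call. = FALSE)
  }
  f <- .ob_props(smiles)$formula[1]
  # strip charge annotations OpenBabel appends (none expected here)
  sub("[+-]+$", "", f)
}

#' Count SMARTS pattern matches in a molecule
#'
#' @param smiles A single SMILES string.
#' @param smarts A SMARTS pattern.
#' @param unique Count unique atom sets rather than raw mappings.
#' @return Integer match count.
#' @export
count_smarts <- function(smiles, smarts, unique = TRUE) {
  n <- ChemmineOB::smartsSearch_OB(.ob_mol(smiles), smarts,
                                   uniqueMatches = unique)
  as.integer(n)
}

# ---- molecular formula arithmetic -----------------------------------------

#' Parse a molecular formula into element counts
#'
#' @param formula Formula string such as `"C6H12O3"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula)
    stop("cannot parse formula: ", formula, call. = FALSE)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)[unique(el)] -> v
  out <- as.integer(v)
  names(out) <- names(v)
  out
}

#' Combine element-count vectors
#'
#' `formula_add()` sums any number of parsed formulas (use negative counts via
#' [formula_scale()] to subtract); `formula_string()` renders counts back to a
#' Hill-order string.
#'
#' @param ... Named integer vectors from [parse_formula()].
#' @return Named integer vector.
#' @export
formula_add <- function(...) {
  vs <- list(...)
  els <- unique(unlist(lapply(vs, names)))
  out <- vapply(els, function(e)
    sum(vapply(vs, function(v) if (e %in% names(v)) v[[e]] else 0L,
               integer(1))), integer(1))
  out[out != 0L]
}

#' @rdname formula_add
#' @param counts Named integer vector.
#' @param k Integer multiplier.
#' @export
formula_scale <- function(counts, k) {
  out <- counts * as.integer(k)
  storage.mode(out) <- "integer"
  out
}

#' @rdname formula_add
#' @export
formula_string <- function(counts) {
  counts <- counts[counts != 0L]
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c("C", if ("H" %in% els) "H", sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(vapply(ord, function(e)
    paste0(e, if (counts[[e]] != 1L) counts[[e]] else ""), character(1)),
    collapse = "")
}
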