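# Levenshtein distance with backtrace: the metric behind the domain
# architecture search. Operates on vectors of single-character tokens;
# the edit script is the chimera-design instruction list.

#' Levenshtein distance and edit script between two strings
#'
#' Computes the minimal number of single-character delete/replace/add edits
#' turning `a` into `b`, plus one script achieving it. Backtrace
#' tie-breaking prefers replace over delete over add. Script operations are
#' emitted in decreasing position order so that every position refers to the
#' original query string `a` (0-based) and sequential application with
#' [apply_edit_script()] is well defined.
#'
#' @param a,b Character scalars (any Unicode strings; empty allowed).
#' @return A list with `distance` (integer) and `script` (data frame with
#'   columns `op` in `delete`/`replace`/`add`, `pos`, `char`).
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L,
            is.character(b), length(b) == 1L)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  if (m > 0L && n > 0L) {
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        cost <- if (av[i] == bv[j]) 0L else 1L
        D[i + 1L, j + 1L] <- min(D[i, j] + cost,       # match / replace
                                 D[i, j + 1L] + 1L,    # delete a[i]
                                 D[i + 1L, j] + 1L)    # add b[j]
      }
    }
  }
  ops <- list()
  i <- m; j <- n
  while (i > 0L || j > 0L) {
    here <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == D[i, j] + (if (av[i] == bv[j]) 0L else 1L)) {
      if (av[i] != bv[j])
        ops[[length(ops) + 1L]] <- data.frame(op = "replace", pos = i - 1L,
                                              char = bv[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == D[i, j + 1L] + 1L) {
      ops[[length(ops) + 1L]] <- data.frame(op = "delete", pos = i - 1L,
                                            char = av[i])
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- data.frame(op = "add", pos = i,
                                            char = bv[j])
      j <- j - 1L
    }
  }
  script <- if (length(ops)) do.call(rbind, ops)
            else data.frame(op = character(0), pos = integer(0),
                            char = character(0))
  list(distance = D[m + 1L, n + 1L], script = script)
}

#' Apply an edit script to a string
#'
#' Operations are applied in the order given; positions refer to the
#' original string, which scripts from [levenshtein()] guarantee by listing
#' edits in decreasing position order.
#'
#' @param a Character scalar the script was computed against.
#' @param script Edit script data frame from [levenshtein()].
#' @return The edited string.
#' @export
apply_edit_script <- function(a, script) {
  v <- strsplit(a, "")[[1]]
  for (k in seq_len(nrow(script))) {
    op <- script$op[k]; pos <- script$pos[k]; ch <- script$char[k]
    if (op == "delete") {
      v <- v[-(pos + 1L)]
    } else if (op == "replace") {
      v[pos + 1L] <- ch
    } else if (op == "add") {
      v <- append(v, ch, after = pos)
    } else stop("unknown edit op: ", op, call. = FALSE)
  }
  paste(v, collapse = "")
}
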