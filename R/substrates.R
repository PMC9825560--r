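# Substrate library: editable TSV tables mapping starter, extender and
# amino-acid codes to structures.

.residue_template_re <-
  "^(N[0-9]?)(.*?)(\\[C@{1,2}H\\][0-9]?|C)(\\((.*)\\))?C\\(=O\\)S$"

.parse_residue_template <- function(code, smiles) {
  m <- regexec(.residue_template_re, smiles)[[1]]
  if (m[1] == -1L)
    stop("amino-acid entry '", code, "' does not follow the residue template ",
         "N...C(=O)S: ", smiles, call. = FALSE)
  g <- regmatches(smiles, regexec(.residue_template_re, smiles))[[1]]
  alpha <- g[4]
  stereo <- if (grepl("@@", alpha)) "@@" else if (grepl("@", alpha)) "@" else NULL
  alpha_ring <- sub("^\\[C@{1,2}H\\]|^C", "", alpha)
  list(code = code,
       smiles = smiles,
       n_pre = g[2],                       # "N" or "N1" (proline)
       pre = g[3],                         # atoms between N and C-alpha
       stereo = stereo,                    # "@" / "@@" / NULL
       alpha_ring = alpha_ring,            # ring-closure digit on C-alpha
       side = if (nzchar(g[6])) g[6] else NULL,
       cyclic = nzchar(g[2]) && grepl("[0-9]", g[2]))
}

#' Read a substrate table
#'
#' Loads a TSV file with columns `code`, `smiles`, `role`, `display_name`
#' (UTF-8, `#` comments allowed) and validates every entry: starters must be
#' acyl thioesters ending in the attachment motif `C(=O)S`, extender
#' fragments must carry exactly one `[*]` attachment point, and amino acids
#' must follow the residue template `N...C(=O)S` with the alpha-amine and
#' acyl carbon as the two marked reaction sites. Every structure must parse
#' in the chemistry backend.
#'
#' @param path Path to a TSV file; defaults to the table shipped with the
#'   package.
#' @return A `substrate_table` object.
#' @seealso [resolve_starter()], [resolve_extender()], [resolve_amino_acid()]
#' @export
read_substrate_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "substrates.tsv", package = "megasynth")
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("code", "smiles", "role", "display_name")
  if (!all(need %in% names(df)))
    stop("substrate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$code))
    stop("duplicate substrate codes: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
         call. = FALSE)
  starters <- list(); extenders <- list(); aminos <- list()
  for (i in seq_len(nrow(df))) {
    code <- df$code[i]; smi <- df$smiles[i]; role <- df$role[i]
    if (role == "starter") {
      if (!endsWith(smi, "C(=O)S"))
        stop("starter '", code, "' must end with the thioester motif C(=O)S",
             call. = FALSE)
      canonical_smiles(smi)  # must parse
      starters[[code]] <- list(code = code, smiles = smi,
                               body = substr(smi, 1L, nchar(smi) - 6L),
                               display_name = df$display_name[i])
    } else if (role == "extender") {
      n_attach <- lengths(regmatches(smi, gregexpr("\\[\\*\\]", smi)))
      if (n_attach != 1L)
        stop("extender '", code, "' must carry exactly one [*] attachment ",
             "point, found ", n_attach, call. = FALSE)
      branch <- sub("\\[\\*\\]", "", smi, fixed = FALSE)
      if (branch == "[H]") branch <- ""
      if (nzchar(branch)) canonical_smiles(branch, strict = FALSE)
      extenders[[code]] <- list(code = code, smiles = smi, branch = branch,
                                display_name = df$display_name[i])
    } else if (role == "amino_acid") {
      canonical_smiles(smi)
      rec <- .parse_residue_template(code, smi)
      rec$display_name <- df$display_name[i]
      aminos[[code]] <- rec
    } else {
      stop("unknown role '", role, "' for code '", code, "'", call. = FALSE)
    }
  }
  structure(list(starters = starters, extenders = extenders,
                 amino_acids = aminos, path = path, table = df),
            class = "substrate_table")
}

#' @export
print.substrate_table <- function(x, ...) {
  cat("<substrate_table> ", length(x$starters), " starters, ",
      length(x$extenders), " extenders, ", length(x$amino_acids),
      " amino acids\n", sep = "")
  invisible(x)
}

#' Write a substrate table back to TSV
#'
#' Round-trips with [read_substrate_table()]: writing and re-reading yields
#' identical mappings.
#'
#' @param table A `substrate_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_substrate_table <- function(table, path) {
  stopifnot(inherits(table, "substrate_table"))
  utils::write.table(table$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# The bundled table, cached per session.
.megasynth_env <- new.env(parent = emptyenv())

#' Default bundled substrate table
#' @return A `substrate_table`.
#' @export
default_substrates <- function() {
  if (is.null(.megasynth_env$substrates))
    .megasynth_env$substrates <- read_substrate_table()
  .megasynth_env$substrates
}

.nearest_codes <- function(code, known, k = 3L) {
  if (length(known) == 0L) return(character(0))
  d <- utils::adist(code, known)[1, ]
  known[order(d)][seq_len(min(k, length(known)))]
}

.unknown_code_stop <- function(code, known, what) {
  near <- .nearest_codes(code, known)
  stop("unknown ", what, " code '", code, "'",
       if (length(near)) paste0("; nearest known codes: ",
                                paste(near, collapse = ", ")),
       call. = FALSE)
}

#' Resolve substrate codes to structures
#'
#' `resolve_starter()` returns the acyl group to be bound as a thioester,
#' `resolve_extender()` the alpha-substituent fragment inserted during a
#' Claisen extension (`mal` is the unsubstituted parent), and
#' `resolve_amino_acid()` the residue record with its marked alpha-amine and
#' acyl carbon. Unknown codes are errors naming the nearest known codes; in
#' lenient mode they fall back to `ace`/`mal`/`gly` with a warning.
#'
#' @param code Substrate code token, e.g. `"prop"`, `"mmal"`, `"gly"`.
#' @param table A `substrate_table`; defaults to the bundled one.
#' @param lenient Substitute a neutral default instead of erroring.
#' @return A list record describing the resolved substrate.
#' @export
resolve_starter <- function(code, table = default_substrates(),
                            lenient = FALSE) {
  rec <- table$starters[[code]]
  if (is.null(rec)) {
    if (!lenient) .unknown_code_stop(code, names(table$starters), "starter")
    warning("unknown starter '", code, "': substituting 'ace' (lenient mode)",
            call. = FALSE)
    rec <- table$starters[["ace"]]
  }
  rec
}

#' @rdname resolve_starter
#' @export
resolve_extender <- function(code, table = default_substrates(),
                             lenient = FALSE) {
  rec <- table$extenders[[code]]
  if (is.null(rec)) {
    if (!lenient) .unknown_code_stop(code, names(table$extenders), "extender")
    warning("unknown extender '", code, "': substituting 'mal' (lenient mode)",
            call. = FALSE)
    rec <- table$extenders[["mal"]]
  }
  rec
}

#' @rdname resolve_starter
#' @export
resolve_amino_acid <- function(code, table = default_substrates(),
                               lenient = FALSE) {
  rec <- table$amino_acids[[code]]
  if (is.null(rec)) {
    if (!lenient) .unknown_code_stop(code, names(table$amino_acids),
                                     "amino-acid")
    warning("unknown amino acid '", code, "': substituting 'gly' ",
            "(lenient mode)", call. = FALSE)
    rec <- table$amino_acids[["gly"]]
  }
  rec
}

# Reductive-domain stereo conventions (editable data file).
kr_stereo_map <- function() {
  if (is.null(.megasynth_env$kr_stereo)) {
    path <- system.file("extdata", "kr_stereo.tsv", package = "megasynth")
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    df$beta_stereo[df$beta_stereo == "."] <- NA
    df$alpha_stereo[df$alpha_stereo == "."] <- NA
    rownames(df) <- df$kr_type
    .megasynth_env$kr_stereo <- df
  }
  .megasynth_env$kr_stereo
}
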