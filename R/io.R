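#' Read a binary character matrix from a text file
#'
#' Plain format is whitespace-separated 0/1 rows; CSV/TSV use comma/tab.
#' A first header line of character names and a first column of species
#' names are auto-detected by their non-binary tokens; missing names
#' default to `s1..sn` / `c1..cm`. Species are rows and characters are
#' columns; transposed input is never auto-detected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"plain"`.
#' @return a binary matrix (see [cppp_matrix()]).
#' @export
read_cppp_matrix <- function(path, format = c("auto", "csv", "tsv", "plain")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext == "tsv") "tsv"
      else "plain"
  }
  sep <- switch(format, csv = ",", tsv = "\t", plain = NULL)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  toks <- lapply(lines, function(l) {
    tk <- if (is.null(sep)) strsplit(trimws(l), "[[:space:]]+")[[1L]]
      else strsplit(l, sep, fixed = TRUE)[[1L]]
    trimws(tk)
  })
  is_bin <- function(x) x %in% c("0", "1")
  # a header line contains a non-binary token beyond the first position
  # (a lone non-binary first token is a species name, not a header)
  has_header <- !all(is_bin(toks[[1L]][-1L]))
  header <- NULL
  if (has_header) {
    header <- toks[[1L]]
    toks <- toks[-1L]
    if (!length(toks)) stop("matrix file has a header but no rows")
  }
  has_rownames <- !all(vapply(toks, function(t) is_bin(t[1L]), logical(1)))
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in matrix file (line ",
         which(widths != widths[1L])[1L] + has_header, ")")
  rn <- NULL
  if (has_rownames) {
    rn <- vapply(toks, `[`, character(1), 1L)
    toks <- lapply(toks, `[`, -1L)
  }
  n <- length(toks); m <- length(toks[[1L]])
  M <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    bad <- which(!is_bin(toks[[i]]))
    if (length(bad))
      stop("non-binary token '", toks[[i]][bad[1L]], "' at line ",
           i + has_header, ", column ", bad[1L] + has_rownames)
    M[i, ] <- as.integer(toks[[i]])
  }
  if (!is.null(header)) {
    cn <- header
    if (length(cn) == m + 1L) cn <- cn[-1L] # leading id column name
    if (length(cn) != m) stop("header has ", length(cn),
                              " names for ", m, " columns")
    colnames(M) <- cn
  }
  if (!is.null(rn)) rownames(M) <- rn
  cppp_matrix(M)
}

#' Write a binary matrix
#' @param M a binary matrix.
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"plain"` (whitespace separated).
#' @export
write_cppp_matrix <- function(M, path, format = c("plain", "csv", "tsv")) {
  format <- match.arg(format)
  M <- cppp_matrix(M)
  sep <- switch(format, csv = ",", tsv = "\t", plain = " ")
  header <- paste(c("id", colnames(M)), collapse = sep)
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rownames(M)[i], M[i, ]), collapse = sep), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read forbidden-persistence constraints
#'
#' One pair per line, `species character`, whitespace separated; blank
#' lines and `#` comments are ignored. Names are resolved against `M` and
#' every constrained cell must be 0.
#'
#' @param path file path.
#' @param M the binary matrix the constraints refer to.
#' @return a [cppp_constraints()] object.
#' @export
read_cppp_constraints <- function(path, M) {
  M <- cppp_matrix(M)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(cppp_constraints())
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("constraint line ", bad[1L],
                        " does not have exactly two tokens")
  sp <- vapply(parts, `[`, character(1), 1L)
  ch <- vapply(parts, `[`, character(1), 2L)
  check_constraints(M, cppp_constraints(character = ch, species = sp))
}

#' Write constraints
#' @param constraints a [cppp_constraints()] object.
#' @param path output path.
#' @export
write_cppp_constraints <- function(constraints, path) {
  lines <- if (nrow(constraints))
    paste(constraints$species, constraints$character) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Export an instance as a general character compatibility problem
#'
#' The constrained persistent phylogeny instance maps to the three-state
#' general character compatibility (GCC) case with cell state sets `{1}`
#' (the species has the character), `{0}` (constrained zero: the character
#' may never appear on the species' root path) and `{0, 2}` (unconstrained
#' zero: never gained, or gained and then lost, state 2), under the allowed
#' transitions 0 -> 1 and 1 -> 2.
#'
#' @param M a binary matrix.
#' @param constraints optional [cppp_constraints()].
#' @return an object of class `"cppp_gcc"`: list with `species`,
#'   `characters`, `cells` (character matrix over `"1"`, `"0"`, `"0/2"`),
#'   and `transitions`.
#' @export
export_gcc <- function(M, constraints = NULL) {
  M <- cppp_matrix(M)
  constraints <- check_constraints(M, constraints)
  mask <- constraint_mask(M, constraints)
  cells <- matrix("0/2", nrow(M), ncol(M), dimnames = dimnames(M))
  cells[M == 1L] <- "1"
  cells[mask] <- "0"
  structure(list(species = rownames(M), characters = colnames(M),
                 cells = cells,
                 transitions = list(c(0L, 1L), c(1L, 2L))),
            class = "cppp_gcc")
}

#' Write a GCC instance as JSON
#' @param gcc a `"cppp_gcc"` from [export_gcc()].
#' @param path output path.
#' @export
write_gcc_json <- function(gcc, path) {
  sets <- list("1" = list(1L), "0" = list(0L), "0/2" = list(0L, 2L))
  cells <- lapply(gcc$species, function(s) {
    row <- lapply(gcc$characters, function(ch) unlist(sets[[gcc$cells[s, ch]]]))
    names(row) <- gcc$characters
    row
  })
  names(cells) <- gcc$species
  obj <- list(species = gcc$species, characters = gcc$characters,
              cells = cells,
              transitions = lapply(gcc$transitions, function(t)
                list(from = t[1L], to = t[2L])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a red-black or conflict graph in DOT format
#' @param x a `"cppp_rbgraph"` (black = solid, red = dashed) or a
#'   `"cppp_conflict"` graph.
#' @param path output path.
#' @export
export_dot <- function(x, path) {
  if (inherits(x, "cppp_rbgraph")) {
    style <- ifelse(x$edges$color == "red", " [style=dashed,color=red]", "")
    lines <- c("graph rb {",
               sprintf('  "%s" -- "%s"%s;', x$edges$species,
                       x$edges$character, style), "}")
  } else if (inherits(x, "cppp_conflict")) {
    body <- if (nrow(x$edges))
      sprintf('  "%s" -- "%s";', x$edges[, 1L], x$edges[, 2L])
    else sprintf('  "%s";', x$characters)
    lines <- c("graph conflict {", body, "}")
  } else stop("unsupported graph object")
  writeLines(lines, path)
  invisible(path)
}
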