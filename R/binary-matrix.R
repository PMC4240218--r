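#' Validate and normalize a binary character matrix
#'
#' Instances are binary matrices with species as rows and characters as
#' columns: `M[s, c] = 1` means species `s` possesses character `c`.
#' Row and column names are the species and character identifiers; when
#' missing they default to `s1..sn` and `c1..cm`. Entries must be 0 or 1.
#'
#' @param x a matrix (or object coercible to one) of 0/1 entries.
#' @return an integer matrix with unique, non-empty dimnames.
#' @examples
#' cppp_matrix(rbind(c(1, 0), c(1, 1), c(0, 1)))
#' @export
cppp_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("matrix must have at least one species and one character")
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("matrix entries must all be 0 or 1")
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicated species names")
  if (anyDuplicated(colnames(x))) stop("duplicated character names")
  x
}

#' Forbidden-persistence constraints
#'
#' A constraint `(c, s)` forbids character `c` from ever appearing on the
#' path from the root to the node of species `s`: neither `s` nor any of its
#' ancestors may have gained `c`. Constrained cells must satisfy
#' `M[s, c] = 0`.
#'
#' @param character character names, one per constraint.
#' @param species species names, parallel to `character`.
#' @return a data frame of class `"cppp_constraints"` with columns
#'   `character` and `species`.
#' @export
cppp_constraints <- function(character = base::character(0),
                             species = base::character(0)) {
  if (length(character) != length(species))
    stop("'character' and 'species' must have the same length")
  out <- data.frame(character = as.character(character),
                    species = as.character(species),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  class(out) <- c("cppp_constraints", "data.frame")
  out
}

# Normalize the `constraints` argument accepted throughout the package and
# check it against M: unknown names and constraints on 1-cells are errors.
check_constraints <- function(M, constraints) {
  if (is.null(constraints)) constraints <- cppp_constraints()
  if (!inherits(constraints, "cppp_constraints"))
    constraints <- cppp_constraints(constraints$character, constraints$species)
  bad_c <- setdiff(constraints$character, colnames(M))
  if (length(bad_c)) stop("unknown character in constraints: ",
                          paste(bad_c, collapse = ", "))
  bad_s <- setdiff(constraints$species, rownames(M))
  if (length(bad_s)) stop("unknown species in constraints: ",
                          paste(bad_s, collapse = ", "))
  if (nrow(constraints)) {
    vals <- M[cbind(match(constraints$species, rownames(M)),
                    match(constraints$character, colnames(M)))]
    if (any(vals != 0L)) {
      i <- which(vals != 0L)[1L]
      stop("invalid constraint (", constraints$character[i], ", ",
           constraints$species[i], "): matrix entry is 1, must be 0")
    }
  }
  constraints
}

# n x m logical mask of constrained cells.
constraint_mask <- function(M, constraints) {
  mask <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  if (nrow(constraints))
    mask[cbind(match(constraints$species, rownames(M)),
               match(constraints$character, colnames(M)))] <- TRUE
  mask
}

#' Remove duplicated rows and columns
#'
#' Duplicates are never removed implicitly by the solvers; callers (and the
#' command-line `--dedup` flag) use this helper, which reports the mapping
#' from removed species/characters to their kept representative.
#'
#' @param M a binary matrix (see [cppp_matrix()]).
#' @return a list with the reduced `matrix`, and `row_map`/`col_map` named
#'   character vectors mapping every original name to the kept name.
#' @export
dedup_matrix <- function(M) {
  M <- cppp_matrix(M)
  rkey <- apply(M, 1L, paste, collapse = "")
  ckey <- apply(M, 2L, paste, collapse = "")
  rkeep <- !duplicated(rkey)
  ckeep <- !duplicated(ckey)
  row_map <- rownames(M)[match(rkey, rkey[rkeep])]
  names(row_map) <- rownames(M)
  col_map <- colnames(M)[ckeep][match(ckey, ckey[ckeep])]
  names(col_map) <- colnames(M)
  list(matrix = M[rkeep, ckeep, drop = FALSE],
       row_map = row_map, col_map = col_map)
}

# --- signed character labels -------------------------------------------------

# Signed characters are strings "c+" / "c-" (gain / loss of character c).
parse_signed <- function(x) {
  sign <- substr(x, nchar(x), nchar(x))
  if (any(!sign %in% c("+", "-")))
    stop("signed character must end in '+' or '-': ",
         paste(x[!sign %in% c("+", "-")], collapse = ", "))
  list(character = substr(x, 1L, nchar(x) - 1L), sign = sign)
}

signed <- function(character, sign) paste0(character, sign)

# A c-reduction is an ordered vector of signed characters in which each
# label occurs at most once and a loss never precedes its gain.
validate_reduction <- function(seq, characters) {
  if (!length(seq)) return(invisible(seq))
  ps <- parse_signed(seq)
  if (anyDuplicated(seq))
    stop("invalid c-reduction: repeated signed character")
  unknown <- setdiff(ps$character, characters)
  if (length(unknown))
    stop("unknown character in c-reduction: ", paste(unknown, collapse = ", "))
  for (ch in unique(ps$character[ps$sign == "-"])) {
    i_minus <- which(seq == signed(ch, "-"))
    i_plus <- which(seq == signed(ch, "+"))
    if (length(i_plus) && i_minus < i_plus)
      stop("invalid c-reduction: ", signed(ch, "-"), " precedes ",
           signed(ch, "+"))
  }
  invisible(seq)
}
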