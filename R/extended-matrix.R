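#' Build the extended matrix of an instance
#'
#' The extended matrix replaces each character `c` by a conjugate column
#' pair `(c+, c-)` recording gain and loss. For a species `s`:
#' `M[s, c] = 1` gives the completed pair `(1, 0)` (gained, not lost);
#' `M[s, c] = 0` with `(c, s)` constrained gives `(0, 0)` (never gained on
#' the path to `s`); an unconstrained 0 gives the incomplete pair `(?, ?)`,
#' which a solver later completes to `(0, 0)` (not persistent) or `(1, 1)`
#' (gained then lost, i.e. persistent for `s`). Incomplete cells are stored
#' as `NA` and serialized as `"?"`.
#'
#' @param M a binary matrix (see [cppp_matrix()]).
#' @param constraints optional [cppp_constraints()].
#' @return an object of class `"cppp_extmat"`: a list with `cells` (integer
#'   `n x 2m` matrix, `NA` = undecided), `species`, `characters`, and the
#'   logical constraint `mask`.
#' @examples
#' M <- cppp_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1)))
#' extend_matrix(M)
#' @export
extend_matrix <- function(M, constraints = NULL) {
  M <- cppp_matrix(M)
  constraints <- check_constraints(M, constraints)
  mask <- constraint_mask(M, constraints)
  n <- nrow(M); m <- ncol(M)
  cells <- matrix(NA_integer_, n, 2L * m)
  rownames(cells) <- rownames(M)
  colnames(cells) <- as.vector(rbind(paste0(colnames(M), "+"),
                                     paste0(colnames(M), "-")))
  for (j in seq_len(m)) {
    one <- M[, j] == 1L
    cells[one, 2L * j - 1L] <- 1L
    cells[one, 2L * j] <- 0L
    con <- mask[, j]
    cells[con, 2L * j - 1L] <- 0L
    cells[con, 2L * j] <- 0L
  }
  structure(list(cells = cells, species = rownames(M),
                 characters = colnames(M), mask = mask),
            class = "cppp_extmat")
}

pair_cols <- function(j) c(2L * j - 1L, 2L * j)

char_index <- function(ext, character) {
  j <- match(character, ext$characters)
  if (is.na(j)) stop("unknown character: ", character)
  j
}

species_index <- function(ext, species) {
  i <- match(species, ext$species)
  if (is.na(i)) stop("unknown species: ", species)
  i
}

#' Complete one conjugate pair
#'
#' @param ext an extended matrix from [extend_matrix()].
#' @param species,character the cell pair to complete.
#' @param mode `"not-persistent"` completes to `(0, 0)`, `"persistent"` to
#'   `(1, 1)`.
#' @return the updated extended matrix.
#' @export
complete_pair <- function(ext, species, character,
                          mode = c("not-persistent", "persistent")) {
  mode <- match.arg(mode)
  i <- species_index(ext, species)
  j <- char_index(ext, character)
  if (!is.na(ext$cells[i, 2L * j - 1L]))
    stop("pair (", species, ", ", character, ") is already completed")
  if (mode == "persistent" && ext$mask[i, j])
    stop("constraint violation: (", character, ", ", species,
         ") cannot be completed as persistent")
  v <- if (mode == "persistent") 1L else 0L
  ext$cells[i, pair_cols(j)] <- v
  ext
}

# Count / locate incomplete pairs; a pair is incomplete iff its c+ cell is NA
# (the two cells of a pair are always both NA or both set).
incomplete_pairs <- function(ext) {
  plus <- ext$cells[, seq(1L, ncol(ext$cells), by = 2L), drop = FALSE]
  idx <- which(is.na(plus), arr.ind = TRUE)
  data.frame(species = ext$species[idx[, 1L]],
             character = ext$characters[idx[, 2L]],
             stringsAsFactors = FALSE)
}

# Recover the original binary matrix from a fresh (or partially completed)
# extended matrix: M[s, c] = 1 iff the pair is (1, 0).
ext_to_matrix <- function(ext) {
  m <- length(ext$characters)
  M <- matrix(0L, length(ext$species), m,
              dimnames = list(ext$species, ext$characters))
  for (j in seq_len(m)) {
    p <- ext$cells[, 2L * j - 1L]
    q <- ext$cells[, 2L * j]
    M[which(!is.na(p) & p == 1L & q == 0L), j] <- 1L
  }
  M
}

#' Does a fully completed matrix admit a directed perfect phylogeny?
#'
#' A 0/1 matrix admits a perfect phylogeny rooted at the all-zero state iff
#' no two columns jointly exhibit all three configurations (0,1), (1,0) and
#' (1,1) across species. Applied to the `2m` columns of a completed extended
#' matrix this is exactly the persistency criterion: the instance admits a
#' (constrained) persistent perfect phylogeny iff some completion of its
#' extended matrix passes this test.
#'
#' @param x a completed `"cppp_extmat"` (no `?` cells) or a plain 0/1 matrix.
#' @return `TRUE` or `FALSE`.
#' @export
admits_directed_pp <- function(x) {
  A <- if (inherits(x, "cppp_extmat")) x$cells else as.matrix(x)
  if (anyNA(A)) stop("matrix is not fully completed: '?' cells remain")
  storage.mode(A) <- "numeric"
  has11 <- crossprod(A) > 0
  has10 <- crossprod(A, 1 - A) > 0 # (1,0): col i = 1, col j = 0
  forbidden <- has11 & has10 & t(has10)
  diag(forbidden) <- FALSE
  !any(forbidden)
}
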