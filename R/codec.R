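# Conformation codecs: absolute direction encoding, the first-occurrence
# canonical ("non-isomorphic") encoding, 4-bit packing, and Hamming
# proximity matching.

coords_of <- function(x) {
  if (inherits(x, "hp_conformation")) return(x$coords)
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Absolute direction encoding
#'
#' Encodes a conformation as the sequence of basis indices of the
#' displacements between consecutive monomers (0-based, following the fixed
#' v1..v12 order of the lattice).  Translation-invariant; rotations of the
#' same structure still produce different absolute encodings.
#'
#' @param x An `hp_conformation` or an n x 3 coordinate matrix.
#' @param lattice An `hp_lattice`.
#' @return Integer vector of n - 1 direction indices in
#'   `0:(nrow(lattice$basis) - 1)`.
#' @examples
#' absolute_encode(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' @export
absolute_encode <- function(x, lattice = fcc_lattice()) {
  coords <- coords_of(x)
  n <- nrow(coords)
  if (n < 2L) return(integer(0))
  steps <- coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE]
  if (any(steps < -1L | steps > 1L))
    stop("chain constraint violated: a step is not a basis vector")
  key <- (steps[, 1] + 1L) + 3L * (steps[, 2] + 1L) + 9L * (steps[, 3] + 1L) + 1L
  idx <- lattice$lut[key]
  if (anyNA(idx))
    stop("chain constraint violated: a step is not a basis vector")
  idx - 1L
}

#' Decode an absolute encoding to coordinates
#'
#' Cumulative sum of basis vectors from `start`; the exact inverse of
#' [absolute_encode()] for the same start point.
#'
#' @param codes Integer vector of 0-based direction indices.
#' @param start Integer vector of length 3.
#' @param lattice An `hp_lattice`.
#' @return An (length(codes) + 1) x 3 integer coordinate matrix.
#' @export
absolute_decode <- function(codes, start = c(0L, 0L, 0L),
                            lattice = fcc_lattice()) {
  start <- as_point(start)
  codes <- as.integer(codes)
  nb <- nrow(lattice$basis)
  if (length(codes) && (anyNA(codes) || any(codes < 0L | codes >= nb)))
    stop("direction codes must lie in 0:", nb - 1L)
  steps <- lattice$basis[codes + 1L, , drop = FALSE]
  coords <- rbind(rep(0L, 3L),
                  if (length(codes)) apply(steps, 2L, cumsum) else NULL)
  coords <- sweep(matrix(as.integer(coords), ncol = 3L), 2L, start, "+")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' First-occurrence canonical (non-isomorphic) encoding
#'
#' Relabels the absolute direction sequence in a single left-to-right pass:
#' each previously unseen absolute direction receives the next unused code,
#' starting at 0.  The result is invariant under translations and under
#' every rotation/reflection of the lattice point group, so conformations
#' that differ only by an isometry share one encoding.  Runs in O(n).
#'
#' Note the map is not injective: distinct (non-isometric) structures can
#' collide on the same code sequence, so equality of encodings is a
#' similarity filter, not a proof of isometry.
#'
#' @param x An `hp_conformation`, a coordinate matrix, or an integer vector
#'   of absolute direction codes.
#' @param lattice An `hp_lattice` (used when `x` carries coordinates).
#' @return Integer vector of n - 1 canonical codes; the first element is
#'   always 0 and each new code exceeds the running maximum by one.
#' @examples
#' sq <- cubic_lattice()
#' dses <- absolute_decode(c(5, 3, 0, 3), lattice = sq)  # D, S, E, S
#' unen <- absolute_decode(c(4, 2, 0, 2), lattice = sq)  # U, N, E, N
#' identical(noniso_encode(dses, sq), noniso_encode(unen, sq))  # TRUE
#' @export
noniso_encode <- function(x, lattice = fcc_lattice()) {
  abs_codes <- if (is.numeric(x) && is.null(dim(x))) as.integer(x)
               else absolute_encode(x, lattice)
  if (length(abs_codes) == 0L) return(integer(0))
  match(abs_codes, unique(abs_codes)) - 1L
}

check_noniso <- function(codes, nb) {
  codes <- as.integer(codes)
  if (length(codes) == 0L) return(codes)
  if (codes[1] != 0L) stop("a canonical encoding must start with 0")
  if (length(codes) > 1L && any(codes[-1L] > cummax(codes)[-length(codes)] + 1L))
    stop("code ", which(codes[-1L] > cummax(codes)[-length(codes)] + 1L)[1] + 1L,
         " violates first-occurrence labeling")
  if (any(codes < 0L | codes >= nb)) stop("codes must lie in 0:", nb - 1L)
  codes
}

#' Canonical coordinates of a first-occurrence encoding
#'
#' Interprets canonical code k as basis vector v(k+1) in the fixed printed
#' basis order (a valid assignment because first occurrences appear in
#' increasing code order) and decodes from the origin.  This yields one
#' fixed representative chain per encoding; because the encoding is lossy,
#' the representative is not guaranteed to be self-avoiding.
#'
#' @param codes Integer vector satisfying the canonical-encoding invariants.
#' @param lattice An `hp_lattice`.
#' @return An (length(codes) + 1) x 3 integer coordinate matrix.
#' @export
canonical_coords <- function(codes, lattice = fcc_lattice()) {
  codes <- check_noniso(codes, nrow(lattice$basis))
  absolute_decode(codes, c(0L, 0L, 0L), lattice)
}

#' Pack an encoding into 4-bit symbols
#'
#' Two codes per byte, earlier symbol in the high nibble; any lattice with
#' at most 16 basis vectors fits.  An odd trailing nibble is zero-padded
#' and the true symbol count kept as an attribute.
#'
#' @param codes Integer vector of codes in 0:15.
#' @return A raw vector of class `hp_packed` with attribute `n_codes`.
#' @examples
#' pack_code(c(0L, 1L, 2L, 1L))  # bytes 01 21
#' @export
pack_code <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) && (anyNA(codes) || any(codes < 0L | codes >= 16L)))
    stop("packed codes must lie in 0:15")
  if (length(codes) == 0L)
    return(structure(raw(0), n_codes = 0L, class = "hp_packed"))
  padded <- c(codes, if (length(codes) %% 2L) 0L)
  hi <- padded[c(TRUE, FALSE)]
  lo <- padded[c(FALSE, TRUE)]
  structure(as.raw(bitwOr(bitwShiftL(hi, 4L), lo)),
            n_codes = length(codes), class = "hp_packed")
}

#' Unpack a 4-bit packed encoding
#'
#' @param packed An `hp_packed` raw vector.
#' @return The original integer code vector.
#' @export
unpack_code <- function(packed) {
  n <- attr(packed, "n_codes")
  if (is.null(n)) n <- 2L * length(packed)
  b <- as.integer(packed)
  out <- integer(2L * length(b))
  out[c(TRUE, FALSE)] <- bitwShiftR(b, 4L)
  out[c(FALSE, TRUE)] <- bitwAnd(b, 15L)
  out[seq_len(n)]
}

#' @export
print.hp_packed <- function(x, ...) {
  cat("<hp_packed>", attr(x, "n_codes"), "symbols:", packed_hex(x), "\n")
  invisible(x)
}

#' Hexadecimal form of a packed encoding
#'
#' @param packed An `hp_packed` raw vector.
#' @return Character scalar, one hex digit per nibble.
#' @export
packed_hex <- function(packed) {
  paste(format(unclass(packed)), collapse = "")
}

as_codes <- function(x) {
  if (inherits(x, "hp_packed") || is.raw(x)) unpack_code(x) else as.integer(x)
}

#' Hamming distance between two encodings
#'
#' Counted over code symbols (nibbles), not raw bits: the distance predates
#' the packing, which is only a storage device, and bit-level counting
#' would weight symbol substitutions unevenly.
#'
#' @param a,b `hp_packed` vectors or integer code vectors of equal symbol
#'   count.
#' @return Integer number of differing symbol positions.
#' @export
hamming_packed <- function(a, b) {
  ca <- as_codes(a); cb <- as_codes(b)
  if (length(ca) != length(cb))
    stop("encodings have different symbol counts (", length(ca), " vs ",
         length(cb), ")")
  cpp_hamming(ca, cb)
}

#' Match an encoding against a local-minima memory
#'
#' TRUE iff some stored encoding lies within `proximity` symbol mismatches
#' of `x`.  This is the revisitation filter of the folding search: a
#' candidate that matches is discarded.
#'
#' @param x An `hp_packed`/integer encoding.
#' @param memory A [minima_memory()] object, or a list/matrix of stored
#'   code vectors.
#' @param proximity Non-negative integer Hamming radius (default: the
#'   memory's own setting, or 3).
#' @return Logical scalar.
#' @export
match_minima <- function(x, memory, proximity = NULL) {
  codes <- as_codes(x)
  if (inherits(memory, "hp_minima_memory")) {
    if (is.null(proximity)) proximity <- memory$proximity
    return(memory_match(memory, codes, proximity))
  }
  if (is.null(proximity)) proximity <- 3L
  if (proximity < 0L) stop("proximity must be >= 0")
  stored <- if (is.matrix(memory)) lapply(seq_len(ncol(memory)), function(j) memory[, j])
            else memory
  for (m in stored) {
    if (hamming_packed(codes, m) <= proximity) return(TRUE)
  }
  FALSE
}
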