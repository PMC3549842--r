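# Lattice geometry: basis vectors, contacts, self-avoiding-walk
# conformations, the lattice point group, and exact SAW enumeration.

new_lattice <- function(name, basis) {
  storage.mode(basis) <- "integer"
  rownames(basis) <- paste0("v", seq_len(nrow(basis)))
  colnames(basis) <- c("x", "y", "z")
  if (anyDuplicated(basis)) stop("basis vectors must be pairwise distinct")
  # direction lookup for component range [-1, 1]: key -> basis index
  lut <- rep(NA_integer_, 27)
  for (i in seq_len(nrow(basis))) {
    v <- basis[i, ]
    if (any(v < -1L | v > 1L)) stop("basis components must lie in [-1, 1]")
    lut[(v[1] + 1L) + 3L * (v[2] + 1L) + 9L * (v[3] + 1L) + 1L] <- i
  }
  # closure under negation
  for (i in seq_len(nrow(basis))) {
    v <- -basis[i, ]
    if (is.na(lut[(v[1] + 1L) + 3L * (v[2] + 1L) + 9L * (v[3] + 1L) + 1L]))
      stop("basis must be closed under negation")
  }
  structure(list(name = name, basis = basis, lut = lut), class = "hp_lattice")
}

#' Face-centered cubic lattice
#'
#' The FCC lattice is generated by the twelve minimal displacement vectors
#' (+-1, +-1, 0), (0, +-1, +-1), (+-1, 0, +-1).  Every site has twelve
#' neighbours, the maximum attainable by a sphere packing, which is why this
#' lattice is the standard discretisation for simplified protein models.
#' The basis row order (v1..v12) is fixed and is relied upon by the absolute
#' direction encoding.
#'
#' @return An object of class `hp_lattice` with fields `name` and `basis`
#'   (a 12 x 3 integer matrix, one displacement per row).
#' @examples
#' fcc_lattice()$basis
#' @export
fcc_lattice <- function() {
  new_lattice("fcc", matrix(c(
     1,  1,  0,
    -1, -1,  0,
    -1,  1,  0,
     1, -1,  0,
     0,  1,  1,
     0,  1, -1,
     0, -1, -1,
     0, -1,  1,
     1,  0,  1,
    -1,  0,  1,
    -1,  0, -1,
     1,  0, -1), ncol = 3, byrow = TRUE))
}

#' Simple cubic lattice
#'
#' Six axis-aligned unit displacements.  Included so that small worked
#' examples expressed in compass/vertical letters (U/D/N/S/E/W, with
#' U = +z, D = -z, N = +y, S = -y, E = +x, W = -x) can be executed; the
#' folding search itself targets the FCC lattice.
#'
#' @return An `hp_lattice` object with a 6 x 3 basis.
#' @export
cubic_lattice <- function() {
  new_lattice("cubic", matrix(c(
     1,  0,  0,
    -1,  0,  0,
     0,  1,  0,
     0, -1,  0,
     0,  0,  1,
     0,  0, -1), ncol = 3, byrow = TRUE))
}

#' @export
print.hp_lattice <- function(x, ...) {
  cat("<hp_lattice>", x$name, "-", nrow(x$basis), "basis vectors\n")
  invisible(x)
}

as_point <- function(p) {
  p <- as.integer(p)
  if (length(p) != 3L || anyNA(p)) stop("a lattice point is three integers")
  p
}

#' Lattice neighbours of a point
#'
#' @param p Integer vector of length 3.
#' @param lattice An `hp_lattice`.
#' @return An integer matrix with one neighbour per row, in basis order.
#' @examples
#' lattice_neighbors(c(0, 0, 0), fcc_lattice())
#' @export
lattice_neighbors <- function(p, lattice = fcc_lattice()) {
  p <- as_point(p)
  sweep(lattice$basis, 2L, p, "+")
}

# basis index of q - p, or NA if not a single lattice step
step_index <- function(p, q, lattice) {
  d <- q - p
  if (any(d < -1L | d > 1L)) return(NA_integer_)
  lattice$lut[(d[1] + 1L) + 3L * (d[2] + 1L) + 9L * (d[3] + 1L) + 1L]
}

#' Are two lattice points in contact?
#'
#' Two points are in contact (neighbours) iff their difference is a basis
#' vector of the lattice.
#'
#' @param p,q Integer vectors of length 3.
#' @param lattice An `hp_lattice`.
#' @return Logical scalar.
#' @examples
#' is_contact(c(0, 0, 0), c(1, 1, 0))          # TRUE on FCC
#' is_contact(c(0, 0, 0), c(1, 0, 0))          # FALSE on FCC
#' @export
is_contact <- function(p, q, lattice = fcc_lattice()) {
  !is.na(step_index(as_point(p), as_point(q), lattice))
}

#' Construct a lattice conformation
#'
#' A conformation is an H/P sequence embedded as a self-avoiding walk: one
#' lattice point per monomer, consecutive monomers in lattice contact
#' (chain constraint), all points distinct (self-avoidance).  The
#' constructor checks shapes only; use [validate_conformation()] for the
#' geometric constraints.
#'
#' @param sequence Character scalar over the alphabet {H, P} (or a character
#'   vector of single letters).
#' @param coords Integer matrix, one row (x, y, z) per monomer.
#' @return An object of class `hp_conformation` with fields `sequence`,
#'   `coords` and the cached logical vector `is_h`.
#' @examples
#' conformation("HHHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' @export
conformation <- function(sequence, coords) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  letters <- strsplit(sequence, "")[[1]]
  if (length(letters) == 0L) stop("sequence must be non-empty")
  if (!all(letters %in% c("H", "P")))
    stop("sequence must use the alphabet {H, P}")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (anyNA(coords)) stop("coordinates must be integers")
  if (ncol(coords) != 3L || nrow(coords) != length(letters))
    stop("coords must be an n x 3 matrix matching the sequence length")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(sequence = sequence, coords = coords,
                 is_h = letters == "H"),
            class = "hp_conformation")
}

#' @export
print.hp_conformation <- function(x, ...) {
  cat("<hp_conformation>", nchar(x$sequence), "monomers,",
      sum(x$is_h), "hydrophobic\n")
  cat(" ", x$sequence, "\n")
  invisible(x)
}

as_conformation <- function(x) {
  if (inherits(x, "hp_conformation")) return(x)
  stop("expected an hp_conformation")
}

coord_key <- function(coords) {
  # exact scalar key per row for |coord| < 2^15 (any chain we can run)
  off <- 2^15
  (coords[, 1] + off) + (coords[, 2] + off) * 2^16 + (coords[, 3] + off) * 2^32
}

#' Validate a conformation against the chain and self-avoidance constraints
#'
#' @param conf An `hp_conformation`.
#' @param lattice An `hp_lattice`.
#' @return A list of class `hp_validation`: `valid` (logical),
#'   `chain_violations` (1-based step indices i where coords\[i+1\] - coords\[i\]
#'   is not a basis vector) and `collisions` (1-based monomer indices that
#'   re-occupy an earlier point).
#' @examples
#' validate_conformation(conformation("HH", rbind(c(0, 0, 0), c(2, 0, 0))))
#' @export
validate_conformation <- function(conf, lattice = fcc_lattice()) {
  conf <- as_conformation(conf)
  n <- nrow(conf$coords)
  chain <- integer(0)
  if (n > 1L) {
    steps <- conf$coords[-1L, , drop = FALSE] - conf$coords[-n, , drop = FALSE]
    bad <- steps < -1L | steps > 1L
    key <- (steps[, 1] + 1L) + 3L * (steps[, 2] + 1L) + 9L * (steps[, 3] + 1L) + 1L
    key[rowSums(bad) > 0L] <- NA_integer_
    idx <- ifelse(is.na(key), NA_integer_, lattice$lut[pmax(key, 1L)])
    chain <- as.integer(which(unname(is.na(idx))))
  }
  collisions <- as.integer(which(duplicated(conf$coords, MARGIN = 1L)))
  structure(list(valid = length(chain) == 0L && length(collisions) == 0L,
                 chain_violations = chain, collisions = collisions),
            class = "hp_validation")
}

#' @export
print.hp_validation <- function(x, ...) {
  if (x$valid) cat("valid self-avoiding walk\n")
  else cat("invalid:", length(x$chain_violations), "chain violation(s) at step(s)",
           paste(x$chain_violations, collapse = ","), "|",
           length(x$collisions), "collision(s) at monomer(s)",
           paste(x$collisions, collapse = ","), "\n")
  invisible(x)
}

assert_valid <- function(conf, lattice) {
  v <- validate_conformation(conf, lattice)
  if (!v$valid)
    stop("invalid conformation: ", length(v$chain_violations),
         " chain violation(s), ", length(v$collisions), " collision(s)")
  invisible(conf)
}

#' A lattice symmetry operation
#'
#' @param rotation 3 x 3 signed-integer matrix (determinant +-1).
#' @param translation Integer vector of length 3.
#' @return An object of class `hp_symmetry`.
#' @export
symmetry_op <- function(rotation, translation = c(0L, 0L, 0L)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "integer"
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  structure(list(rotation = rotation, translation = as_point(translation)),
            class = "hp_symmetry")
}

#' All point-group symmetries of a lattice
#'
#' Enumerates the signed 3 x 3 permutation matrices that map the basis set
#' onto itself bijectively.  For both the FCC and the cubic lattice this is
#' the full octahedral group of 48 operations (rotations and reflections);
#' filter on `det == +1` for proper rotations only.
#'
#' @param lattice An `hp_lattice`.
#' @return A list of `hp_symmetry` operations (zero translation).
#' @export
lattice_symmetries <- function(lattice = fcc_lattice()) {
  lapply(cpp_lattice_symmetries(lattice$basis), symmetry_op)
}

#' Apply a symmetry operation to a conformation
#'
#' Rotates every coordinate then translates; the H/P sequence is unchanged.
#' Errors if the rotation does not map the lattice basis onto itself.
#'
#' @param conf An `hp_conformation`.
#' @param op An `hp_symmetry`.
#' @param lattice An `hp_lattice`.
#' @return The transformed `hp_conformation`.
#' @export
apply_symmetry <- function(conf, op, lattice = fcc_lattice()) {
  conf <- as_conformation(conf)
  if (!inherits(op, "hp_symmetry")) stop("op must be an hp_symmetry")
  img <- lattice$basis %*% t(op$rotation)
  ok <- apply(img, 1L, function(v) {
    all(v >= -1L & v <= 1L) &&
      !is.na(lattice$lut[(v[1] + 1L) + 3L * (v[2] + 1L) + 9L * (v[3] + 1L) + 1L])
  })
  if (!all(ok)) stop("rotation does not preserve the lattice basis")
  coords <- conf$coords %*% t(op$rotation)
  coords <- sweep(coords, 2L, op$translation, "+")
  conformation(conf$sequence, coords)
}

.saw_cap <- c(reduced = 8L, full = 5L)

#' Enumerate self-avoiding walks
#'
#' Exhaustive depth-first enumeration of all self-avoiding walks of `n`
#' monomers starting at the origin.  With `reduce_symmetry = TRUE`, exactly
#' one representative per rotation/reflection class is produced (the
#' lexicographically minimal direction sequence over the lattice point
#' group; its first step is always basis vector v1).  The conformation
#' space grows so fast that enumeration is capped at small `n`
#' (8 reduced / 5 unreduced); it exists as an exact optimality oracle, not
#' as a folding method.
#'
#' @param n Number of monomers.
#' @param lattice An `hp_lattice`.
#' @param reduce_symmetry Emit one walk per symmetry class?
#' @return A list of n x 3 integer coordinate matrices.
#' @examples
#' length(enumerate_saws(3, reduce_symmetry = FALSE))  # 132 on FCC
#' @export
enumerate_saws <- function(n, lattice = fcc_lattice(), reduce_symmetry = TRUE) {
  n <- as.integer(n)
  cap <- if (reduce_symmetry) .saw_cap[["reduced"]] else .saw_cap[["full"]]
  if (n < 1L) stop("n must be >= 1")
  if (n > cap)
    stop("n exceeds the enumeration cap (", cap, if (reduce_symmetry)
      " with" else " without", " symmetry reduction)")
  flat <- cpp_enumerate_saws(n, lattice$basis, reduce_symmetry)
  n_walks <- nrow(flat) / n
  lapply(seq_len(n_walks), function(w) {
    m <- flat[((w - 1L) * n + 1L):(w * n), , drop = FALSE]
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
}

#' Count self-avoiding walks
#'
#' @inheritParams enumerate_saws
#' @return Number of walks (double; exact for the supported `n`).
#' @export
saw_count <- function(n, lattice = fcc_lattice(), reduce_symmetry = TRUE) {
  n <- as.integer(n)
  cap <- if (reduce_symmetry) .saw_cap[["reduced"]] else .saw_cap[["full"]]
  if (n < 1L || n > cap) stop("n out of range for enumeration")
  cpp_saw_count(n, lattice$basis, reduce_symmetry)
}

#' Exact optimal HP energy by exhaustive enumeration
#'
#' Minimises the HP contact energy over every self-avoiding walk of the
#' sequence, enumerating one representative per symmetry class (the energy
#' is an isometry invariant).  Practical only for short chains; capped at
#' 9 monomers.
#'
#' @param sequence H/P string.
#' @param lattice An `hp_lattice`.
#' @return A list with `energy` (the exact optimum, an integer <= 0) and
#'   `n_walks` (number of symmetry classes enumerated).
#' @examples
#' optimal_saw_energy("HHHH")
#' @export
optimal_saw_energy <- function(sequence, lattice = fcc_lattice()) {
  letters <- strsplit(sequence, "")[[1]]
  if (!all(letters %in% c("H", "P"))) stop("sequence must be over {H, P}")
  if (length(letters) > 9L) stop("exhaustive optimum capped at 9 monomers")
  res <- cpp_optimal_energy(letters == "H", lattice$basis)
  res$energy <- as.integer(res$energy)
  res
}
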