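# HP contact energy and the distance-based search fitness, with an
# incremental delta under single-monomer moves.

#' HP contact energy of a conformation
#'
#' E = sum over pairs (i, j), i + 1 < j, of c_ij * e_ij, where c_ij = 1 iff
#' monomers i and j are lattice contacts and e_ij = -1 iff both are H
#' (0 otherwise).  Equivalently, minus the number of non-consecutive H-H
#' contacts: minimising E maximises the hydrophobic core's contact count.
#'
#' @param conf A valid `hp_conformation`.
#' @param lattice An `hp_lattice`.
#' @param e_hh Interaction energy of an H-H contact (default -1; the H-P and
#'   P-P terms of the model are 0).
#' @return Integer energy (<= 0 for the default parameters).
#' @examples
#' rhombus <- conformation("HHHH",
#'   rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' hp_energy(rhombus)  # -1: one non-consecutive H-H contact
#' @export
hp_energy <- function(conf, lattice = fcc_lattice(), e_hh = -1L) {
  conf <- as_conformation(conf)
  assert_valid(conf, lattice)
  contacts <- -cpp_hp_energy(conf$coords, conf$is_h, lattice$basis)
  as.integer(e_hh * contacts)
}

#' Search fitness of a conformation
#'
#' The guide function of the folding search: over every non-consecutive
#' H-H pair it sums `dv(i, j)^2` where `dv(i, j) = d(i, j) - 2` and
#' `d(i, j)` is the squared Euclidean distance between monomers i and j.
#' On FCC every reachable pairwise squared distance is even and >= 2, so
#' `dv >= 0` and the fitness is 0 exactly when every non-consecutive H-H
#' pair is in contact (a perfectly packed hydrophobic core).  The energy of
#' a structure is still scored by [hp_energy()]; the fitness only drives
#' the search.
#'
#' @param conf A valid `hp_conformation`.
#' @param lattice An `hp_lattice`.
#' @param literal Use the deviation `dv = d^2 - 2` (squared distance
#'   squared again minus two) instead of the default `dv = d - 2`.  Under
#'   the literal form a contact pair contributes (2^2 - 2)^2 = 4, so a
#'   packed core is not a zero of the function; the option exists for
#'   comparison only.
#' @return Non-negative numeric fitness (an integer value).
#' @examples
#' rhombus <- conformation("HHHH",
#'   rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' hp_fitness(rhombus)  # 8
#' @export
hp_fitness <- function(conf, lattice = fcc_lattice(), literal = FALSE) {
  conf <- as_conformation(conf)
  assert_valid(conf, lattice)
  cpp_fitness(conf$coords, conf$is_h, literal)
}

#' A single-monomer move
#'
#' @param i 1-based monomer index.
#' @param target Integer vector of length 3, the proposed new position.
#' @return A list of class `hp_move`.
#' @export
hp_move <- function(i, target) {
  structure(list(i = as.integer(i), target = as_point(target)),
            class = "hp_move")
}

# is the move applicable: target free and in contact with the chain
# neighbours of i (ends: the single interior neighbour)?
move_applicable <- function(conf, move, lattice) {
  n <- nrow(conf$coords)
  i <- move$i
  if (i < 1L || i > n || n < 2L) return(FALSE)
  if (any(coord_key(conf$coords) ==
          coord_key(matrix(move$target, 1L)))) return(FALSE)
  left <- if (i > 1L) is_contact(conf$coords[i - 1L, ], move$target, lattice) else TRUE
  right <- if (i < n) is_contact(conf$coords[i + 1L, ], move$target, lattice) else TRUE
  left && right
}

#' Fitness change of a single-monomer move
#'
#' Computed incrementally, touching only the pairs that involve the moved
#' monomer; identical to recomputing [hp_fitness()] on the moved
#' conformation.  Moves of P monomers never change the fitness.
#'
#' @param conf A valid `hp_conformation`.
#' @param move An `hp_move` (or list with fields `i` and `target`).
#' @param lattice An `hp_lattice`.
#' @param literal See [hp_fitness()].
#' @return Numeric fitness difference (after - before).
#' @export
delta_fitness <- function(conf, move, lattice = fcc_lattice(), literal = FALSE) {
  conf <- as_conformation(conf)
  assert_valid(conf, lattice)
  if (!move_applicable(conf, move, lattice))
    stop("move is not applicable: target must be free and in contact with ",
         "the chain neighbour(s) of monomer ", move$i)
  cpp_delta_fitness(conf$coords, conf$is_h, move$i - 1L,
                    as_point(move$target), literal)
}

#' Apply a single-monomer move
#'
#' @inheritParams delta_fitness
#' @return The moved `hp_conformation`.
#' @export
apply_move <- function(conf, move, lattice = fcc_lattice()) {
  conf <- as_conformation(conf)
  if (!move_applicable(conf, move, lattice)) stop("move is not applicable")
  coords <- conf$coords
  coords[move$i, ] <- as_point(move$target)
  conformation(conf$sequence, coords)
}
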