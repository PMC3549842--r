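# Long-term memory of visited local minima and the bounded elite archive of
# runner-up conformations.  Both are environment-backed so the search loop
# mutates them in place.

#' Long-term memory of local minima
#'
#' Stores the canonical (first-occurrence) encodings of a sampled fraction
#' of the local minima met during a search.  Candidate conformations whose
#' encoding falls within `proximity` Hamming symbols of a stored entry are
#' discarded by the search (revisitation control).
#'
#' @param proximity Hamming radius used at query time (default 3).
#' @param rate Fraction of offered local minima actually stored
#'   (default 0.05, i.e. 5 percent).
#' @return An object of class `hp_minima_memory`.
#' @export
minima_memory <- function(proximity = 3L, rate = 0.05) {
  if (proximity < 0L) stop("proximity must be >= 0")
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  mem <- new.env(parent = emptyenv())
  mem$mat <- NULL          # (n - 1) x capacity; one encoding per column
  mem$used <- 0L
  mem$encountered <- 0L
  mem$proximity <- as.integer(proximity)
  mem$rate <- rate
  class(mem) <- "hp_minima_memory"
  mem
}

memory_grow <- function(mem, ncode) {
  if (is.null(mem$mat)) {
    mem$mat <- matrix(0L, nrow = max(ncode, 1L), ncol = 64L)
  } else if (mem$used == ncol(mem$mat)) {
    mem$mat <- cbind(mem$mat, matrix(0L, nrow = nrow(mem$mat),
                                     ncol = ncol(mem$mat)))
  }
  invisible(mem)
}

#' Unconditionally store an encoding in a minima memory
#'
#' @param mem An `hp_minima_memory`.
#' @param codes Integer code vector (or `hp_packed`).
#' @return The memory, invisibly.
#' @export
memory_store <- function(mem, codes) {
  codes <- as_codes(codes)
  memory_grow(mem, length(codes))
  if (length(codes) != nrow(mem$mat))
    stop("encoding length does not match this memory")
  mem$used <- mem$used + 1L
  mem$mat[, mem$used] <- codes
  invisible(mem)
}

#' Offer a detected local minimum to the memory
#'
#' Stores the encoding with probability `mem$rate` (a Bernoulli draw from
#' the session RNG) and always increments the encountered counter.
#'
#' @inheritParams memory_store
#' @return Logical: was the encoding stored?
#' @export
memory_offer <- function(mem, codes) {
  mem$encountered <- mem$encountered + 1L
  store <- mem$rate > 0 && runif(1L) < mem$rate
  if (store) memory_store(mem, codes)
  store
}

#' Query a minima memory
#'
#' @inheritParams memory_store
#' @param proximity Hamming radius; defaults to the memory's setting.
#' @return TRUE iff a stored encoding is within `proximity` mismatches.
#' @export
memory_match <- function(mem, codes, proximity = NULL) {
  if (mem$used == 0L) return(FALSE)
  codes <- as_codes(codes)
  if (is.null(proximity)) proximity <- mem$proximity
  if (length(codes) != nrow(mem$mat))
    stop("encoding length does not match this memory")
  cpp_match_any(codes, mem$mat, mem$used, as.integer(proximity))
}

#' Number of stored encodings
#' @param mem An `hp_minima_memory`.
#' @return Integer count.
#' @export
memory_size <- function(mem) mem$used

#' @export
print.hp_minima_memory <- function(x, ...) {
  cat("<hp_minima_memory>", x$used, "stored /", x$encountered,
      "encountered (rate", x$rate, ", proximity", x$proximity, ")\n")
  invisible(x)
}

#' Elite archive of runner-up conformations
#'
#' A bounded priority store of the "second best" candidates generated but
#' not selected during the search, ordered best-fitness-first with ties
#' broken towards the more recent iteration.  At stagnation the search
#' retreats to the best live element (see [select_from_elite_set()]).
#'
#' @param capacity Maximum number of stored conformations; at capacity the
#'   worst element is evicted on insertion (default 5000).
#' @return An object of class `hp_elite_set`.
#' @export
elite_set <- function(capacity = 5000L) {
  if (capacity < 1L) stop("capacity must be >= 1")
  es <- new.env(parent = emptyenv())
  es$capacity <- as.integer(capacity)
  alloc <- min(64L, es$capacity)
  es$fitness <- numeric(alloc)
  es$iteration <- integer(alloc)
  es$coords <- vector("list", alloc)
  es$used <- 0L
  class(es) <- "hp_elite_set"
  es
}

# amortized growth keeps per-push vector copies proportional to live size
elite_grow <- function(es) {
  alloc <- length(es$fitness)
  new_alloc <- min(es$capacity, 2L * alloc)
  if (new_alloc > alloc) {
    es$fitness <- c(es$fitness, numeric(new_alloc - alloc))
    es$iteration <- c(es$iteration, integer(new_alloc - alloc))
    es$coords <- c(es$coords, vector("list", new_alloc - alloc))
  }
  invisible(es)
}

# indices of live slots ordered best-first: min fitness, ties -> later iteration
elite_order <- function(es) {
  idx <- seq_len(es$used)
  idx[order(es$fitness[idx], -es$iteration[idx])]
}

#' Insert a conformation into an elite set
#'
#' @param es An `hp_elite_set`.
#' @param coords n x 3 integer coordinate matrix.
#' @param fitness Fitness of the conformation.
#' @param iteration Iteration at which it was generated.
#' @return TRUE if inserted (FALSE when worse than everything in a full set).
#' @export
elite_push <- function(es, coords, fitness, iteration) {
  if (es$used < es$capacity) {
    if (es$used == length(es$fitness)) elite_grow(es)
    slot <- es$used + 1L
    es$used <- slot
  } else {
    # worst-ordered live slot: max fitness, ties -> earliest iteration
    live_f <- es$fitness[seq_len(es$used)]
    w <- which(live_f == max(live_f))
    worst <- if (length(w) > 1L) w[which.min(es$iteration[w])] else w
    # insert only if strictly better-ordered than the current worst
    if (fitness > es$fitness[worst] ||
        (fitness == es$fitness[worst] && iteration <= es$iteration[worst]))
      return(FALSE)
    slot <- worst
  }
  es$fitness[slot] <- fitness
  es$iteration[slot] <- as.integer(iteration)
  es$coords[[slot]] <- coords
  TRUE
}

#' Best element of an elite set
#'
#' @param es An `hp_elite_set`.
#' @return A list (`coords`, `fitness`, `iteration`) or NULL when empty.
#' @export
elite_peek <- function(es) {
  if (es$used == 0L) return(NULL)
  top <- elite_order(es)[1L]
  list(coords = es$coords[[top]], fitness = es$fitness[top],
       iteration = es$iteration[top])
}

elite_remove <- function(es, slots) {
  keep <- setdiff(seq_len(es$used), slots)
  m <- length(keep)
  es$fitness[seq_len(m)] <- es$fitness[keep]
  es$iteration[seq_len(m)] <- es$iteration[keep]
  es$coords[seq_len(m)] <- es$coords[keep]
  if (m < es$used) es$coords[(m + 1L):es$used] <- list(NULL)
  es$used <- m
  invisible(es)
}

#' Pop the best element of an elite set
#'
#' @param es An `hp_elite_set`.
#' @return The removed element (as in [elite_peek()]) or NULL.
#' @export
elite_pop <- function(es) {
  if (es$used == 0L) return(NULL)
  top <- elite_order(es)[1L]
  out <- list(coords = es$coords[[top]], fitness = es$fitness[top],
              iteration = es$iteration[top])
  elite_remove(es, top)
  out
}

#' Release the k best-ordered elements of an elite set
#'
#' Used on a successful retreat: the selected element and its near-ranked
#' peers (similar fitness, temporally proximate) are dropped together so
#' the search does not immediately retreat back into the same region.
#'
#' @param es An `hp_elite_set`.
#' @param k Number of top elements to drop.
#' @return The elite set, invisibly.
#' @export
elite_release <- function(es, k) {
  k <- min(as.integer(k), es$used)
  if (k > 0L) elite_remove(es, elite_order(es)[seq_len(k)])
  invisible(es)
}

#' Number of live elite elements
#' @param es An `hp_elite_set`.
#' @return Integer count.
#' @export
elite_size <- function(es) es$used

#' @export
print.hp_elite_set <- function(x, ...) {
  cat("<hp_elite_set>", x$used, "/", x$capacity, "conformations")
  if (x$used > 0L) cat("; best fitness", min(x$fitness[seq_len(x$used)]))
  cat("\n")
  invisible(x)
}
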