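# The local search: tabu-restricted single-monomer moves guided by the
# distance fitness, long-term memory of local minima with Hamming-proximity
# discarding, and the elite-retreat mechanism for stagnation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Search parameters
#'
#' @param max_iterations Iteration budget of the main loop.
#' @param max_stable Consecutive non-improving iterations that trigger a
#'   stagnation retreat (default 100).
#' @param proximity Hamming radius of the local-minima memory (default 3).
#' @param memory_rate Fraction of detected local minima stored (default
#'   0.05).
#' @param elite_release Fraction of the elite set released on a successful
#'   retreat (default 0.05, minimum one element).
#' @param elite_capacity Bound on the elite archive (default 5000).
#' @param period_h,period_p The monomer-type schedule: `period_h`
#'   consecutive H iterations followed by `period_p` P iterations
#'   (defaults 9 and 1).
#' @param allow_end_moves May the chain ends relocate to any free neighbour
#'   of their single chain neighbour (default TRUE)?
#' @param literal_fitness Use the literal deviation `d^2 - 2`; see
#'   [hp_fitness()].
#' @param max_runner_up Cap on runner-up candidates archived per iteration
#'   (default 3).
#' @param seed Optional integer seed; when given, the whole run is
#'   reproducible.
#' @param trace Keep the per-iteration trace (default TRUE)?
#' @return A list of class `hp_search_params`.
#' @export
search_params <- function(max_iterations = 10000L, max_stable = 100L,
                          proximity = 3L, memory_rate = 0.05,
                          elite_release = 0.05, elite_capacity = 5000L,
                          period_h = 9L, period_p = 1L,
                          allow_end_moves = TRUE, literal_fitness = FALSE,
                          max_runner_up = 3L, seed = NULL, trace = TRUE) {
  p <- list(max_iterations = as.integer(max_iterations),
            max_stable = as.integer(max_stable),
            proximity = as.integer(proximity),
            memory_rate = memory_rate, elite_release = elite_release,
            elite_capacity = as.integer(elite_capacity),
            period_h = as.integer(period_h), period_p = as.integer(period_p),
            allow_end_moves = isTRUE(allow_end_moves),
            literal_fitness = isTRUE(literal_fitness),
            max_runner_up = as.integer(max_runner_up),
            seed = if (!is.null(seed)) as.integer(seed), trace = isTRUE(trace))
  if (p$max_iterations < 1L) stop("max_iterations must be >= 1")
  if (p$max_stable < 1L) stop("max_stable must be >= 1")
  if (p$proximity < 0L) stop("proximity must be >= 0")
  if (p$memory_rate < 0 || p$memory_rate > 1) stop("memory_rate in [0, 1]")
  if (p$elite_release < 0 || p$elite_release > 1) stop("elite_release in [0, 1]")
  if (p$period_h < 0L || p$period_p < 0L || p$period_h + p$period_p < 1L)
    stop("type periods must be non-negative and not both zero")
  class(p) <- "hp_search_params"
  p
}

#' Random self-avoiding initial conformation
#'
#' Grows a seeded random self-avoiding walk step by step, choosing
#' uniformly among the free lattice neighbours of the last monomer and
#' backtracking on dead ends.  On FCC (twelve neighbours) dead ends are
#' rare and the growth practically always succeeds.
#'
#' @param sequence H/P string.
#' @param lattice An `hp_lattice`.
#' @param max_retries Fresh growth attempts before giving up.
#' @return A valid `hp_conformation`.
#' @export
initialize_conformation <- function(sequence, lattice = fcc_lattice(),
                                    max_retries = 100L) {
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  if (n == 0L) stop("sequence must be non-empty")
  if (n == 1L) return(conformation(sequence, matrix(0L, 1L, 3L)))
  basis <- lattice$basis
  nb <- nrow(basis)
  for (retry in seq_len(max_retries)) {
    coords <- matrix(0L, n, 3L)
    occ <- new.env(parent = emptyenv(), size = 2L * n)
    assign("0/0/0", TRUE, envir = occ)
    cand <- vector("list", n)
    cand[[2L]] <- sample.int(nb)
    d <- 2L
    budget <- 200L * n
    while (d >= 2L && d <= n && budget > 0L) {
      budget <- budget - 1L
      placed <- FALSE
      while (length(cand[[d]]) > 0L) {
        b <- cand[[d]][1L]
        cand[[d]] <- cand[[d]][-1L]
        p <- coords[d - 1L, ] + basis[b, ]
        key <- paste(p, collapse = "/")
        if (!exists(key, envir = occ, inherits = FALSE)) {
          coords[d, ] <- p
          assign(key, TRUE, envir = occ)
          d <- d + 1L
          if (d <= n) cand[[d]] <- sample.int(nb)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        d <- d - 1L
        if (d >= 2L)
          rm(list = paste(coords[d, ], collapse = "/"), envir = occ)
      }
    }
    if (d > n) return(conformation(sequence, coords))
  }
  stop("could not grow a self-avoiding walk after ", max_retries, " attempts")
}

#' Monomer type scheduled for an iteration
#'
#' The search alternates blocks of H iterations (fitness-guided, best move
#' first) with blocks of P iterations (uniform random move): `period_h`
#' H iterations, then `period_p` P iterations, repeating.
#'
#' @param iteration 1-based iteration counter.
#' @param period_h,period_p Block lengths (defaults 9 and 1).
#' @return "H" or "P".
#' @examples
#' sapply(1:12, select_monomer_type)  # H x9, P, H, H
#' @export
select_monomer_type <- function(iteration, period_h = 9L, period_p = 1L) {
  if (period_h == 0L) return("P")
  if (period_p == 0L) return("H")
  pos <- (as.integer(iteration) - 1L) %% (period_h + period_p)
  if (pos < period_h) "H" else "P"
}

# canonical encoding straight from coordinates (hot path; assumes validity)
noniso_of_coords <- function(coords, lattice) {
  cpp_noniso_coords(coords, lattice$lut)
}

resample_tenure <- function(n) {
  hi <- max(4L, n %/% 4L)
  if (hi <= 4L) 4L else sample(4L:hi, 1L)
}

initialize_tabu <- function(state) {
  state$tabu_expiry <- rep(0L, state$n)
  state$tenure <- resample_tenure(state$n)
  k <- state$tabu_n + 1L
  if (k > length(state$tabu_start)) {       # doubling growth
    state$tabu_start <- c(state$tabu_start, integer(length(state$tabu_start)))
    state$tabu_tenure <- c(state$tabu_tenure, integer(length(state$tabu_tenure)))
  }
  state$tabu_start[k] <- state$iteration + 1L
  state$tabu_tenure[k] <- state$tenure
  state$tabu_n <- k
  invisible(state)
}

#' Create a search state
#'
#' Builds the mutable state of one search run: a random initial
#' conformation, empty tabu list, fresh local-minima memory and elite set.
#' The state is an environment; the operation functions
#' ([generate_moves()], [select_move()], [select_from_elite_set()], ...)
#' mutate it in place.  [run_fold()] drives the full loop.
#'
#' @param sequence H/P string.
#' @param params An [search_params()] list.
#' @param lattice An `hp_lattice`.
#' @return An environment of class `hp_search_state`.
#' @export
search_state <- function(sequence, params = search_params(),
                         lattice = fcc_lattice()) {
  letters <- strsplit(sequence, "")[[1]]
  if (length(letters) == 0L || !all(letters %in% c("H", "P")))
    stop("sequence must be a non-empty string over {H, P}")
  state <- new.env(parent = emptyenv())
  state$sequence <- sequence
  state$is_h <- letters == "H"
  state$n <- length(letters)
  state$lattice <- lattice
  state$params <- params
  init <- initialize_conformation(sequence, lattice)
  state$coords <- init$coords
  state$initial_coords <- init$coords
  state$iteration <- 0L
  state$tabu_start <- integer(16L)
  state$tabu_tenure <- integer(16L)
  state$tabu_n <- 0L
  initialize_tabu(state)
  state$memory <- minima_memory(params$proximity, params$memory_rate)
  state$elite <- elite_set(params$elite_capacity)
  state$cur_fitness <- cpp_fitness(state$coords, state$is_h,
                                   params$literal_fitness)
  state$cur_energy <- cpp_hp_energy(state$coords, state$is_h, lattice$basis)
  state$best_fitness <- state$cur_fitness
  state$best_energy <- state$cur_energy
  state$best_coords <- state$coords
  state$stagnation_ref <- state$cur_fitness
  state$non_improving <- 0L
  state$discards <- 0L
  state$minima_detected <- 0L
  state$minima_stored <- 0L
  state$h_cache <- NULL
  state$retreat_log <- list()
  class(state) <- "hp_search_state"
  state
}

# all moves of one type, before tabu filtering (cached for H between moves)
moves_raw <- function(state, type) {
  if (type == "H" && !is.null(state$h_cache)) return(state$h_cache)
  mv <- cpp_generate_moves(state$coords, state$is_h, state$lattice$basis,
                           type == "H", state$params$allow_end_moves,
                           state$params$literal_fitness)
  if (type == "H") state$h_cache <- mv
  mv
}

#' Generate the applicable moves of an iteration
#'
#' All single-monomer relocations for non-tabu monomers of the selected
#' type whose target point is free and in lattice contact with both chain
#' neighbours (ends: the single interior neighbour).  H moves carry their
#' incremental fitness delta and are sorted best (most negative) first.
#'
#' @param state An `hp_search_state`.
#' @param type "H" or "P".
#' @return A numeric matrix with columns `i`, `x`, `y`, `z`, `delta`
#'   (possibly zero rows).
#' @export
generate_moves <- function(state, type = "H") {
  if (!type %in% c("H", "P")) stop("type must be \"H\" or \"P\"")
  mv <- moves_raw(state, type)
  keep <- state$tabu_expiry[mv[, 1L]] <= state$iteration
  mv <- mv[keep, , drop = FALSE]
  if (type == "H" && nrow(mv) > 1L)
    mv <- mv[order(mv[, 5L]), , drop = FALSE]
  mv
}

# runner-up rows: moves whose delta equals the smallest delta strictly
# worse than the selected one's, capped
runner_up_rows <- function(moves, selected_row, cap) {
  deltas <- moves[, 5L]
  worse <- which(deltas > deltas[selected_row])
  if (length(worse) == 0L) return(moves[0L, , drop = FALSE])
  second <- min(deltas[worse])
  rows <- worse[deltas[worse] == second]
  moves[head(rows, cap), , drop = FALSE]
}

#' Select the move of an iteration
#'
#' Walks the candidate list best-first.  Each candidate conformation is
#' built, canonically encoded and checked against the local-minima memory;
#' matching candidates are discarded (revisitation control).  The first
#' surviving candidate is returned after the runner-up candidates of the
#' iteration have been offered to the elite set.  If every candidate is
#' discarded (or the list is empty), the iteration stalls: the
#' non-improving counter is pushed past `max_stable` so the stagnation
#' handler fires.
#'
#' @param state An `hp_search_state`.
#' @param moves Move matrix from [generate_moves()] (best-first for H;
#'   shuffle beforehand for the uniform P rule).
#' @return A list (`i`, `target`, `delta`, `codes`) or NULL on stagnation.
#' @export
select_move <- function(state, moves) {
  mem <- state$memory
  for (r in seq_len(nrow(moves))) {
    cand <- state$coords
    cand[moves[r, 1L], ] <- as.integer(moves[r, 2:4])
    codes <- noniso_of_coords(cand, state$lattice)
    if (mem$used > 0L &&
        cpp_match_any(codes, mem$mat, mem$used, mem$proximity)) {
      state$discards <- state$discards + 1L
      next
    }
    update_elite_set(state, runner_up_rows(moves, r, state$params$max_runner_up))
    return(list(i = as.integer(moves[r, 1L]),
                target = as.integer(moves[r, 2:4]),
                delta = moves[r, 5L], codes = codes))
  }
  state$non_improving <- state$params$max_stable + 1L
  NULL
}

#' Offer runner-up candidates to the elite set
#'
#' Each candidate conformation is encoded and checked against the
#' local-minima memory; only unmatched candidates are archived (with the
#' fitness they would have after the move and the current iteration).
#'
#' @param state An `hp_search_state`.
#' @param candidates Move matrix rows (columns `i`, `x`, `y`, `z`,
#'   `delta`).
#' @return Number of candidates inserted, invisibly.
#' @export
update_elite_set <- function(state, candidates) {
  inserted <- 0L
  mem <- state$memory
  for (r in seq_len(nrow(candidates))) {
    cand <- state$coords
    cand[candidates[r, 1L], ] <- as.integer(candidates[r, 2:4])
    codes <- noniso_of_coords(cand, state$lattice)
    if (mem$used > 0L &&
        cpp_match_any(codes, mem$mat, mem$used, mem$proximity)) next
    if (elite_push(state$elite, cand,
                   state$cur_fitness + candidates[r, 5L], state$iteration))
      inserted <- inserted + 1L
  }
  invisible(inserted)
}

#' Retreat target from the elite set
#'
#' Repeatedly examines the best live element, re-encoding it and
#' re-checking it against the (possibly grown) local-minima memory;
#' matched elements are popped and dropped.  The first unmatched element is
#' returned after a fixed fraction of the top elements (at least one, so
#' including the returned element itself) is released.  Returns NULL when
#' the elite set exhausts; the caller then falls back to the best-so-far
#' conformation.
#'
#' @param state An `hp_search_state`.
#' @return A list (`coords`, `fitness`, `iteration`) or NULL.
#' @export
select_from_elite_set <- function(state) {
  es <- state$elite
  mem <- state$memory
  while (elite_size(es) > 0L) {
    top <- elite_peek(es)
    codes <- noniso_of_coords(top$coords, state$lattice)
    if (mem$used > 0L &&
        cpp_match_any(codes, mem$mat, mem$used, mem$proximity)) {
      elite_pop(es)
      next
    }
    k <- max(1L, ceiling(state$params$elite_release * elite_size(es)))
    elite_release(es, k)
    return(top)
  }
  NULL
}

#' Detect (and possibly store) a local minimum
#'
#' The current conformation is a local minimum when its fitness is strictly
#' below that of every applicable H move (tabu ignored: local optimality is
#' a property of the landscape, not of the short-term memory).  A detected
#' minimum's canonical encoding is offered to the local-minima memory,
#' which stores it with probability `memory_rate`.
#'
#' @param state An `hp_search_state`.
#' @param h_moves Optional precomputed matrix of all H moves for the
#'   current conformation.
#' @return A list (`detected`, `stored`), invisibly.
#' @export
detect_and_store_local_minimum <- function(state, h_moves = NULL) {
  if (is.null(h_moves)) h_moves <- moves_raw(state, "H")
  detected <- nrow(h_moves) == 0L || all(h_moves[, 5L] > 0)
  stored <- FALSE
  if (detected) {
    state$minima_detected <- state$minima_detected + 1L
    stored <- memory_offer(state$memory,
                           noniso_of_coords(state$coords, state$lattice))
    if (stored) state$minima_stored <- state$minima_stored + 1L
  }
  invisible(list(detected = detected, stored = stored))
}

#' Run the folding search
#'
#' Executes the full local search: per iteration it selects the scheduled
#' monomer type, generates the applicable moves, selects a move through the
#' memory filter (archiving runner-ups in the elite set), performs it,
#' updates the incremental fitness/energy, and detects local minima.  When
#' `max_stable` iterations pass without a fitness improvement the tabu list
#' is re-initialized and the search retreats to the best elite conformation
#' (or restarts from the best-so-far conformation when the elite set is
#' exhausted).  The best conformation is tracked by HP energy; the fitness
#' only steers.
#'
#' @param sequence H/P string (or an `hp_conformation`, whose sequence is
#'   used).
#' @param params An [search_params()] list.
#' @param lattice An `hp_lattice`.
#' @return A list of class `hp_fold_result`: the best conformation and its
#'   energy/fitness, counters (discards, retreats, restarts, minima), the
#'   final memory and elite objects, the per-iteration trace, the retreat
#'   log, and everything needed to replay the run.
#' @examples
#' res <- run_fold("HPHHPH", search_params(max_iterations = 200, seed = 1))
#' res$best_energy
#' @export
run_fold <- function(sequence, params = search_params(),
                     lattice = fcc_lattice()) {
  if (inherits(sequence, "hp_conformation")) sequence <- sequence$sequence
  if (!inherits(params, "hp_search_params")) stop("params must come from search_params()")
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- search_state(sequence, params, lattice)
  ni <- params$max_iterations
  tr_event <- integer(ni)          # 1 move, 2 stall
  tr_monomer <- rep(NA_integer_, ni)
  tr_x <- rep(NA_integer_, ni); tr_y <- rep(NA_integer_, ni); tr_z <- rep(NA_integer_, ni)
  tr_fitness <- numeric(ni); tr_energy <- integer(ni); tr_best <- integer(ni)
  tr_min <- logical(ni); tr_stored <- logical(ni)
  basis <- lattice$basis

  period <- params$period_h + params$period_p
  for (iter in seq_len(ni)) {
    state$iteration <- iter
    type <- if (params$period_h == 0L) "P"
            else if ((iter - 1L) %% period < params$period_h) "H" else "P"
    mv <- generate_moves(state, type)
    if (type == "P" && nrow(mv) > 1L)
      mv <- mv[sample.int(nrow(mv)), , drop = FALSE]
    sel <- select_move(state, mv)
    if (is.null(sel)) {
      tr_event[iter] <- 2L
    } else {
      i <- sel$i
      de <- if (state$is_h[i])
        cpp_delta_energy(state$coords, state$is_h, i - 1L, sel$target, basis)
      else 0L
      state$coords[i, ] <- sel$target
      state$cur_fitness <- state$cur_fitness + sel$delta
      state$cur_energy <- state$cur_energy + de
      state$tabu_expiry[i] <- iter + state$tenure
      state$h_cache <- NULL
      if (state$cur_energy < state$best_energy) {
        state$best_energy <- state$cur_energy
        state$best_coords <- state$coords
      }
      det <- detect_and_store_local_minimum(state)
      tr_event[iter] <- 1L
      tr_monomer[iter] <- i
      tr_x[iter] <- sel$target[1]; tr_y[iter] <- sel$target[2]; tr_z[iter] <- sel$target[3]
      tr_min[iter] <- det$detected; tr_stored[iter] <- det$stored
    }
    if (state$cur_fitness < state$stagnation_ref) {
      state$stagnation_ref <- state$cur_fitness
      state$non_improving <- 0L
    } else {
      state$non_improving <- state$non_improving + 1L
    }
    if (state$cur_fitness < state$best_fitness)
      state$best_fitness <- state$cur_fitness
    tr_fitness[iter] <- state$cur_fitness
    tr_energy[iter] <- state$cur_energy
    tr_best[iter] <- state$best_energy

    if (state$non_improving >= params$max_stable && iter < ni) {
      initialize_tabu(state)
      ret <- select_from_elite_set(state)
      if (is.null(ret)) {
        src <- "restart"
        new_coords <- state$best_coords
      } else {
        src <- "retreat"
        new_coords <- ret$coords
      }
      state$coords <- new_coords
      state$cur_fitness <- cpp_fitness(new_coords, state$is_h,
                                       params$literal_fitness)
      state$cur_energy <- cpp_hp_energy(new_coords, state$is_h, basis)
      if (state$cur_energy < state$best_energy) {
        state$best_energy <- state$cur_energy
        state$best_coords <- new_coords
      }
      if (state$cur_fitness < state$best_fitness)
        state$best_fitness <- state$cur_fitness
      state$stagnation_ref <- state$cur_fitness
      state$non_improving <- 0L
      state$h_cache <- NULL
      state$retreat_log[[length(state$retreat_log) + 1L]] <-
        list(iteration = iter, source = src, coords = new_coords,
             fitness = state$cur_fitness, energy = state$cur_energy)
    }
  }

  retreats <- state$retreat_log
  retreat_df <- data.frame(
    iteration = vapply(retreats, `[[`, integer(1), "iteration"),
    source = vapply(retreats, `[[`, character(1), "source"),
    fitness = vapply(retreats, `[[`, numeric(1), "fitness"),
    energy = vapply(retreats, `[[`, numeric(1), "energy"))
  trace <- NULL
  if (params$trace)
    trace <- data.frame(
      iteration = seq_len(ni),
      event = c("move", "stall")[tr_event],
      monomer = tr_monomer, x = tr_x, y = tr_y, z = tr_z,
      current_fitness = tr_fitness, current_energy = tr_energy,
      best_energy = tr_best,
      minimum_detected = tr_min, minimum_stored = tr_stored)
  structure(list(
    sequence = sequence,
    best_conformation = conformation(sequence, state$best_coords),
    best_energy = as.integer(state$best_energy),
    best_fitness = state$best_fitness,
    iterations = ni,
    retreats = sum(retreat_df$source == "retreat"),
    restarts = sum(retreat_df$source == "restart"),
    discards = state$discards,
    minima_detected = state$minima_detected,
    minima_stored = state$minima_stored,
    memory_size = memory_size(state$memory),
    elite_size = elite_size(state$elite),
    memory = state$memory,
    elite = state$elite,
    trace = trace,
    retreat_log = retreats,
    retreat_events = retreat_df,
    tabu_log = data.frame(
      start = state$tabu_start[seq_len(state$tabu_n)],
      tenure = state$tabu_tenure[seq_len(state$tabu_n)]),
    initial_coords = state$initial_coords,
    params = params,
    lattice = lattice$name), class = "hp_fold_result")
}

#' @export
print.hp_fold_result <- function(x, ...) {
  cat("<hp_fold_result>", nchar(x$sequence), "monomers,", x$iterations,
      "iterations\n")
  cat("  best energy ", x$best_energy, ", best fitness ", x$best_fitness,
      "\n", sep = "")
  cat("  retreats", x$retreats, "| restarts", x$restarts, "| discards",
      x$discards, "| minima stored", x$minima_stored, "/",
      x$minima_detected, "\n")
  invisible(x)
}
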