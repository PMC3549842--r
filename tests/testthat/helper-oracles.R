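# Shared fixtures and independent brute-force oracles.  The oracles stay
# deliberately naive (double loops over all pairs, literal definitions) so
# they check the optimized implementation from the outside.

FCC <- fcc_lattice()
CUBIC <- cubic_lattice()

# the four-monomer rhombus: one non-consecutive H-H contact
rhombus_conf <- function(sequence = "HHHH") {
  conformation(sequence,
               rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
}

# straight walk along v1
straight_conf <- function(sequence) {
  n <- nchar(sequence)
  conformation(sequence, cbind(0:(n - 1), 0:(n - 1), 0L))
}

random_conformation <- function(n, h_fraction = 0.5, lattice = FCC) {
  seq <- paste(ifelse(runif(n) < h_fraction, "H", "P"), collapse = "")
  initialize_conformation(seq, lattice)
}

naive_hp_energy <- function(conf, lattice = FCC) {
  n <- nrow(conf$coords)
  e <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i + 1 && conf$is_h[i] && conf$is_h[j] &&
        is_contact(conf$coords[i, ], conf$coords[j, ], lattice))
      e <- e - 1L
  }
  e
}

naive_fitness <- function(conf, literal = FALSE) {
  n <- nrow(conf$coords)
  f <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i + 1 && conf$is_h[i] && conf$is_h[j]) {
      d <- sum((conf$coords[i, ] - conf$coords[j, ])^2)
      dv <- if (literal) d^2 - 2 else d - 2
      f <- f + dv^2
    }
  }
  f
}

# brute-force SAW enumeration, independent of the C++ enumerator
r_enumerate_saws <- function(n, lattice = FCC) {
  walks <- list(matrix(0L, 1L, 3L))
  for (step in seq_len(n - 1)) {
    grown <- list()
    for (w in walks) {
      last <- w[nrow(w), ]
      for (b in seq_len(nrow(lattice$basis))) {
        p <- last + lattice$basis[b, ]
        if (!any(w[, 1] == p[1] & w[, 2] == p[2] & w[, 3] == p[3]))
          grown[[length(grown) + 1L]] <- rbind(w, p, deparse.level = 0)
      }
    }
    walks <- grown
  }
  walks
}

walk_signature <- function(coords) paste(t(coords), collapse = ",")

# Independent replay of a fold run from its logged initial conformation,
# moves and retreat targets.  Recomputes occupancy, chain contacts, HP
# energy (via the FCC squared-distance-2 contact rule) and the tabu rule
# from scratch; returns per-iteration energies plus violation counts.
replay_fold <- function(result, is_h) {
  tr <- result$trace
  coords <- result$initial_coords
  n <- nrow(coords)
  keyv <- coords[, 1] * 1e6 + coords[, 2] * 1e3 + coords[, 3] +
    5e8  # exact for |coord| < 500
  energy_of <- function(cc) {
    e <- 0L
    hi <- which(is_h)
    for (a in seq_along(hi)) {
      i <- hi[a]
      for (b in seq_len(a - 1L)) {
        j <- hi[b]
        if (abs(i - j) > 1L &&
            sum((cc[i, ] - cc[j, ])^2) == 2) e <- e - 1L
      }
    }
    e
  }
  contact2 <- function(p, q) sum((p - q)^2) == 2
  retreat_at <- split(result$retreat_log,
                      vapply(result$retreat_log, `[[`, numeric(1), "iteration"))
  epochs <- result$tabu_log
  epoch_idx <- 1L
  last_move <- rep(-Inf, n)
  last_tenure <- rep(0L, n)
  bad_free <- 0L; bad_chain <- 0L; bad_tabu <- 0L; bad_retreat <- 0L
  energies <- integer(nrow(tr))
  retreat_energies <- rep(NA_integer_, nrow(tr))
  cur_e <- energy_of(coords)
  init_energy <- cur_e
  for (r in seq_len(nrow(tr))) {
    iter <- tr$iteration[r]
    while (epoch_idx < nrow(epochs) && epochs$start[epoch_idx + 1L] <= iter)
      epoch_idx <- epoch_idx + 1L
    if (tr$event[r] == "move") {
      i <- tr$monomer[r]
      tgt <- c(tr$x[r], tr$y[r], tr$z[r])
      tkey <- tgt[1] * 1e6 + tgt[2] * 1e3 + tgt[3] + 5e8
      if (any(keyv == tkey)) bad_free <- bad_free + 1L
      ok_l <- i == 1L || contact2(coords[i - 1L, ], tgt)
      ok_r <- i == n || contact2(coords[i + 1L, ], tgt)
      if (!(ok_l && ok_r)) bad_chain <- bad_chain + 1L
      # tabu: a monomer moved at t is frozen until t + tenure, unless the
      # tabu list was re-initialized in between
      if (is.finite(last_move[i]) &&
          last_move[i] >= epochs$start[epoch_idx] &&
          iter < last_move[i] + last_tenure[i]) bad_tabu <- bad_tabu + 1L
      # incremental energy (H moves only affect H-H contacts)
      if (is_h[i]) {
        hj <- which(is_h & abs(seq_len(n) - i) > 1L)
        before <- sum(vapply(hj, function(j) contact2(coords[j, ], coords[i, ]),
                             logical(1)))
        after <- sum(vapply(hj, function(j) contact2(coords[j, ], tgt),
                            logical(1)))
        cur_e <- cur_e - after + before
      }
      coords[i, ] <- tgt
      keyv[i] <- tkey
      last_move[i] <- iter
      last_tenure[i] <- epochs$tenure[epoch_idx]
    }
    energies[r] <- cur_e
    ra <- retreat_at[[as.character(iter)]]
    if (!is.null(ra)) {
      for (ev in ra) {
        coords <- ev$coords
        keyv <- coords[, 1] * 1e6 + coords[, 2] * 1e3 + coords[, 3] + 5e8
        if (anyDuplicated(keyv)) bad_retreat <- bad_retreat + 1L
        cur_e <- energy_of(coords)
        if (cur_e != ev$energy) bad_retreat <- bad_retreat + 1L
        retreat_energies[r] <- cur_e
      }
    }
  }
  list(energies = energies, retreat_energies = retreat_energies,
       init_energy = init_energy, final_coords = coords,
       bad_free = bad_free, bad_chain = bad_chain, bad_tabu = bad_tabu,
       bad_retreat = bad_retreat)
}

# the best-energy trace implied by an independent replay: the running
# minimum over the initial energy, each post-move energy, and each retreat
# target's energy (which counts from the following iteration on)
expected_best_trace <- function(rp) {
  ni <- length(rp$energies)
  out <- integer(ni)
  cur <- rp$init_energy
  for (t in seq_len(ni)) {
    cur <- min(cur, rp$energies[t])
    out[t] <- cur
    if (!is.na(rp$retreat_energies[t])) cur <- min(cur, rp$retreat_energies[t])
  }
  out
}
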