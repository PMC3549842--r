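# helper: a state with fixed coordinates (bypassing random initialization)
fixed_state <- function(sequence, coords, params = search_params()) {
  st <- search_state(sequence, params)
  st$coords <- coords
  st$cur_fitness <- hp_fitness(conformation(sequence, coords))
  st$cur_energy <- hp_energy(conformation(sequence, coords))
  st$h_cache <- NULL
  st$iteration <- 1L
  st
}

test_that("initialization yields valid, seed-reproducible walks", {
  one <- initialize_conformation("H")
  expect_equal(one$coords, matrix(0L, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
  set.seed(9); a <- initialize_conformation("HPHPHPHPHP")
  set.seed(9); b <- initialize_conformation("HPHPHPHPHP")
  expect_identical(a, b)
  set.seed(10)
  for (k in 1:100) {
    conf <- initialize_conformation(generate_fixture_sequence(50, 0.5))
    expect_true(validate_conformation(conf, FCC)$valid)
  }
})

test_that("the monomer-type schedule alternates H and P blocks", {
  expect_equal(sapply(1:9, select_monomer_type), rep("H", 9))
  expect_equal(select_monomer_type(10), "P")
  expect_equal(select_monomer_type(11), "H")
  expect_equal(sapply(1:6, select_monomer_type, period_h = 1, period_p = 1),
               rep(c("H", "P"), 3))
})

test_that("move generation finds the free common contacts of the chain neighbours", {
  st <- fixed_state("HHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)))
  mv <- generate_moves(st, "H")
  mid <- mv[mv[, 1] == 2, , drop = FALSE]
  expect_equal(nrow(mid), 3L)   # (1,1,0) is occupied by the monomer itself
  expect_equal(unname(mid[, 2:4]),
               rbind(c(1, -1, 0), c(1, 0, 1), c(1, 0, -1)))
  # all tabu -> nothing to do
  st$tabu_expiry <- rep(10L, 3)
  expect_equal(nrow(generate_moves(st, "H")), 0L)
})

test_that("end monomers move against their single neighbour, and can be frozen", {
  coords <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  st <- fixed_state("HHH", coords)
  mv <- generate_moves(st, "H")
  expect_true(any(mv[, 1] == 1) && any(mv[, 1] == 3))
  # targets of monomer 1 are free neighbours of monomer 2
  t1 <- mv[mv[, 1] == 1, 2:4, drop = FALSE]
  for (r in seq_len(nrow(t1)))
    expect_true(is_contact(t1[r, ], coords[2, ], FCC))
  st2 <- fixed_state("HHH", coords,
                     search_params(allow_end_moves = FALSE))
  mv2 <- generate_moves(st2, "H")
  expect_true(all(mv2[, 1] == 2))
})

test_that("every generated move preserves self-avoiding-walk validity", {
  set.seed(14)
  for (k in 1:100) {
    conf <- random_conformation(sample(5:20, 1))
    st <- fixed_state(conf$sequence, conf$coords)
    for (type in c("H", "P")) {
      mv <- generate_moves(st, type)
      if (nrow(mv) == 0L) next
      r <- sample.int(nrow(mv), 1)
      moved <- apply_move(conf, hp_move(mv[r, 1], mv[r, 2:4]))
      expect_true(validate_conformation(moved, FCC)$valid)
    }
  }
})

test_that("move selection walks the candidate list through the memory filter", {
  st <- fixed_state("HHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)),
                    search_params(proximity = 0))
  mv <- generate_moves(st, "H")
  sel <- select_move(st, mv)
  expect_equal(sel$i, as.integer(mv[1, 1]))   # best candidate unmatched
  # poison the best candidate's encoding: the runner-up must be chosen
  best <- st$coords; best[mv[1, 1], ] <- as.integer(mv[1, 2:4])
  memory_store(st$memory, noniso_encode(best, FCC))
  sel2 <- select_move(st, mv)
  expect_false(identical(list(sel2$i, sel2$target), list(sel$i, sel$target)))
  expect_gte(st$discards, 1L)
  # empty candidate list signals stagnation
  st$non_improving <- 0L
  expect_null(select_move(st, mv[0, , drop = FALSE]))
  expect_gt(st$non_improving, st$params$max_stable)
})

test_that("elite updates archive unmatched runner-ups with their post-move fitness", {
  st <- fixed_state("HHHH",
                    rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0)),
                    search_params(proximity = 0))
  mv <- generate_moves(st, "H")
  expect_gt(nrow(mv), 1)
  cand <- mv[2, , drop = FALSE]
  update_elite_set(st, cand)
  expect_equal(elite_size(st$elite), 1L)
  expect_equal(elite_peek(st$elite)$fitness,
               st$cur_fitness + unname(cand[1, 5]))
  # a candidate matching the memory is rejected
  poisoned <- st$coords; poisoned[cand[1, 1], ] <- as.integer(cand[1, 2:4])
  memory_store(st$memory, noniso_encode(poisoned, FCC))
  update_elite_set(st, cand)
  expect_equal(elite_size(st$elite), 1L)
})

test_that("retreat selection pops memory-matched elements and releases the top", {
  st <- fixed_state("HHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)),
                    search_params(proximity = 0))
  # one unmatched element: returned, and the release empties the set
  a <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(2L, 2L, 0L))
  elite_push(st$elite, a, fitness = 4, iteration = 1)
  got <- select_from_elite_set(st)
  expect_equal(got$coords, a)
  expect_equal(elite_size(st$elite), 0L)
  # matched top is popped; the second element is returned
  b <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(0L, 2L, 0L))
  elite_push(st$elite, a, fitness = 1, iteration = 2)
  elite_push(st$elite, b, fitness = 7, iteration = 2)
  memory_store(st$memory, noniso_encode(a, FCC))
  got2 <- select_from_elite_set(st)
  expect_equal(got2$coords, b)
  expect_equal(elite_size(st$elite), 0L)
  # exhausted set signals failure
  expect_null(select_from_elite_set(st))
})

test_that("local-minimum detection keys on strictly positive H-move deltas", {
  st <- fixed_state("HHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)),
                    search_params(memory_rate = 1))
  uphill <- cbind(i = 2, x = 1, y = -1, z = 0, delta = 5)
  out <- detect_and_store_local_minimum(st, uphill)
  expect_true(out$detected)
  expect_true(out$stored)          # rate 1: every detection stored
  expect_equal(memory_size(st$memory), 1L)
  flat <- cbind(i = 2, x = 1, y = -1, z = 0, delta = 0)
  expect_false(detect_and_store_local_minimum(st, flat)$detected)
  st0 <- fixed_state("HHH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)),
                     search_params(memory_rate = 0))
  out0 <- detect_and_store_local_minimum(st0, uphill)
  expect_true(out0$detected)
  expect_false(out0$stored)        # rate 0: memory stays empty
  expect_equal(memory_size(st0$memory), 0L)
})

test_that("an all-P chain finishes at energy and fitness zero, deterministically", {
  r <- run_fold("PPPPPPPP", search_params(max_iterations = 500, seed = 4))
  expect_identical(r$best_energy, 0L)
  expect_equal(r$best_fitness, 0)
  expect_equal(r$iterations, 500L)
  r2 <- run_fold("PPPPPPPP", search_params(max_iterations = 500, seed = 4))
  expect_identical(r$trace, r2$trace)
})

test_that("repeated runs with one seed are identical, different seeds differ", {
  s <- "HPHHPHHPHH"
  p <- search_params(max_iterations = 2000, seed = 12)
  a <- run_fold(s, p); b <- run_fold(s, p)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_conformation$coords, b$best_conformation$coords)
  expect_identical(a$retreat_log, b$retreat_log)
  c <- run_fold(s, search_params(max_iterations = 2000, seed = 13))
  expect_false(identical(a$trace, c$trace))
})

test_that("a medium run passes an independent replay of every invariant", {
  set.seed(77)
  s <- generate_fixture_sequence(20, 0.5)
  r <- run_fold(s, search_params(max_iterations = 20000, seed = 21))
  is_h <- strsplit(s, "")[[1]] == "H"
  rp <- replay_fold(r, is_h)
  expect_equal(rp$bad_free, 0L)
  expect_equal(rp$bad_chain, 0L)
  expect_equal(rp$bad_tabu, 0L)
  expect_equal(rp$bad_retreat, 0L)
  expect_equal(rp$energies, r$trace$current_energy)
  expect_equal(r$trace$best_energy, expected_best_trace(rp))
  expect_true(all(diff(r$trace$best_energy) <= 0))
})

test_that("the elite-guided tabu core recovers small-instance optima without the memory", {
  # with revisitation control disabled the search core alone must find the
  # exhaustively enumerated optimum on short chains (see the methods
  # vignette for why the memory radius degenerates at this scale)
  set.seed(1)
  hits <- 0L
  for (k in 1:10) {
    s <- generate_fixture_sequence(8, 0.5, min_h = 3)
    opt <- optimal_saw_energy(s)$energy
    r <- run_fold(s, search_params(max_iterations = 20000, seed = 1000 + k,
                                   memory_rate = 0, trace = FALSE))
    if (r$best_energy == opt) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("longer searches keep improving on a length-50 chain", {
  best_at_1e4 <- numeric(10)
  best_at_1e5 <- numeric(10)
  for (k in 1:10) {
    set.seed(100 + k)
    s <- generate_fixture_sequence(50, 0.5)
    r <- run_fold(s, search_params(max_iterations = 100000, seed = 200 + k))
    expect_true(all(diff(r$trace$best_energy) <= 0))
    best_at_1e4[k] <- r$trace$best_energy[10000]
    best_at_1e5[k] <- r$trace$best_energy[100000]
  }
  expect_lte(mean(best_at_1e5), mean(best_at_1e4))
  expect_gte(sum(best_at_1e5 < best_at_1e4), 6)
})
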