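test_that("absolute encoding follows the printed basis order and is translation invariant", {
  expect_identical(absolute_encode(straight_conf("HHHH")), c(0L, 0L, 0L))
  expect_identical(absolute_encode(rhombus_conf()), c(0L, 3L, 1L))  # v1, v4, v2
  shifted <- rhombus_conf()$coords
  shifted <- sweep(shifted, 2, c(7L, -2L, 5L), "+")
  expect_identical(absolute_encode(shifted), c(0L, 3L, 1L))
  expect_error(absolute_encode(rbind(c(0, 0, 0), c(2, 0, 0))), "chain")
})

test_that("absolute decode is the inverse of encode", {
  expect_equal(absolute_decode(integer(0)), matrix(0L, 1, 3,
               dimnames = list(NULL, c("x", "y", "z"))))
  expect_equal(unname(absolute_decode(c(0L, 0L))),
               rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(2L, 2L, 0L)))
  set.seed(5)
  for (k in 1:50) {
    conf <- random_conformation(sample(2:20, 1))
    codes <- absolute_encode(conf)
    expect_equal(unname(absolute_decode(codes, conf$coords[1, ])),
                 unname(conf$coords))
  }
  expect_error(absolute_decode(12L), "0:11")
})

test_that("the cubic-lattice worked example: two rotated copies share one encoding", {
  # D,S,E,S walk and U,N,E,N walk (U=+z, D=-z, N=+y, S=-y, E=+x, W=-x)
  dses <- absolute_decode(c(5L, 3L, 0L, 3L), lattice = CUBIC)
  unen <- absolute_decode(c(4L, 2L, 0L, 2L), lattice = CUBIC)
  e1 <- noniso_encode(dses, CUBIC)
  e2 <- noniso_encode(unen, CUBIC)
  expect_identical(e1, c(0L, 1L, 2L, 1L))
  expect_identical(e1, e2)
})

test_that("canonical encoding is invariant under translations and all 48 symmetries", {
  ops <- lattice_symmetries(FCC)
  set.seed(31)
  for (k in 1:50) {
    conf <- random_conformation(12)
    ref <- noniso_encode(conf)
    expect_identical(ref[1], 0L)
    for (op in ops) {
      op$translation <- sample(-9:9, 3, replace = TRUE)
      expect_identical(noniso_encode(apply_symmetry(conf, op, FCC)), ref)
    }
  }
  # straight walks collapse to all zeros
  expect_identical(noniso_encode(straight_conf("HHHHH")), rep(0L, 4))
})

test_that("canonical coordinates round-trip through the encoding", {
  expect_equal(unname(canonical_coords(c(0L, 1L, 2L, 1L))),
               unname(absolute_decode(c(0L, 1L, 2L, 1L))))
  expect_equal(nrow(canonical_coords(integer(0))), 1L)
  set.seed(17)
  for (k in 1:100) {
    conf <- random_conformation(sample(3:15, 1))
    e <- noniso_encode(conf)
    expect_identical(noniso_encode(canonical_coords(e)), e)
  }
  expect_error(canonical_coords(c(1L, 0L)), "start with 0")
  expect_error(canonical_coords(c(0L, 2L)), "first-occurrence")
})

test_that("conformations rebuilt from equal encodings have equal energy and fitness", {
  set.seed(19)
  for (k in 1:20) {
    conf <- random_conformation(8, h_fraction = 0.7)
    e <- noniso_encode(conf)
    rebuilt <- canonical_coords(e)
    again <- canonical_coords(noniso_encode(rebuilt, FCC))
    expect_identical(rebuilt, again)
    c1 <- conformation(conf$sequence, rebuilt)
    c2 <- conformation(conf$sequence, again)
    if (validate_conformation(c1, FCC)$valid) {
      expect_identical(hp_energy(c1), hp_energy(c2))
      expect_identical(hp_fitness(c1), hp_fitness(c2))
    }
  }
})

test_that("packing is 4 bits per symbol, high nibble first, and round-trips", {
  p <- pack_code(c(0L, 1L, 2L, 1L))
  expect_identical(unclass(p)[1:2], as.raw(c(0x01, 0x21)))
  expect_identical(packed_hex(p), "0121")
  expect_identical(unpack_code(p), c(0L, 1L, 2L, 1L))
  expect_length(unclass(pack_code(integer(0))), 0L)
  set.seed(41)
  for (k in 1:200) {
    codes <- sample(0:11, sample(1:40, 1), replace = TRUE)
    expect_identical(unpack_code(pack_code(codes)), as.integer(codes))
  }
  expect_error(pack_code(16L), "0:15")
})

test_that("Hamming distance counts differing symbols and matches a naive oracle", {
  expect_identical(hamming_packed(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L)), 0L)
  expect_identical(hamming_packed(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 2L)), 1L)
  expect_identical(hamming_packed(pack_code(c(0L, 3L)), pack_code(c(1L, 3L))), 1L)
  set.seed(47)
  for (k in 1:100) {
    len <- sample(1:30, 1)
    a <- sample(0:11, len, replace = TRUE)
    b <- sample(0:11, len, replace = TRUE)
    expect_identical(hamming_packed(a, b), as.integer(sum(a != b)))
  }
  expect_error(hamming_packed(c(0L, 1L), 0L), "different symbol counts")
})

test_that("memory matching respects the proximity radius", {
  expect_false(match_minima(c(0L, 1L, 2L), list(), proximity = 3))
  expect_true(match_minima(c(0L, 1L, 2L), list(c(0L, 1L, 2L)), proximity = 0))
  base <- c(0L, 1L, 2L, 3L, 4L, 0L, 1L)
  flipped <- base
  flipped[1:4] <- (flipped[1:4] + 1L) %% 12L   # symbol distance exactly 4
  expect_identical(hamming_packed(base, flipped), 4L)
  expect_false(match_minima(base, list(flipped), proximity = 3))
  expect_true(match_minima(base, list(flipped), proximity = 4))

  mem <- minima_memory(proximity = 3)
  memory_store(mem, base)
  expect_true(match_minima(base, mem))
  expect_false(match_minima(flipped, mem))
})

test_that("encoding cost grows about linearly with chain length", {
  set.seed(53)
  short_walk <- absolute_decode(sample(c(0L, 2L, 4L), 99, replace = TRUE))
  long_walk <- absolute_decode(sample(c(0L, 2L, 4L), 9999, replace = TRUE))
  t_short <- system.time(for (k in 1:50) noniso_encode(short_walk, FCC))[3]
  t_long <- system.time(for (k in 1:50) noniso_encode(long_walk, FCC))[3]
  # 100x the length must cost well under 100x the time of the short walk,
  # guarding against accidental superlinear behaviour (generous bound:
  # timers are coarse)
  expect_lt(t_long, max(t_short, 0.002) * 100)
})
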