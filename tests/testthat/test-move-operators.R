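test_that("crossover is suffix surgery with validity verdicts", {
  r <- crossover(conformation(c(1, 1, 1)), conformation(c(3, 3, 3)), cut = 1)
  expect_equal(unclass(r$children[[1]]), c(1, 3, 3))
  expect_equal(unclass(r$children[[2]]), c(3, 1, 1))
  # identical parents reproduce themselves at every cut
  set.seed(31)
  p <- conformation(random_valid_dirs(10))
  for (cut in 1:8) {
    rr <- crossover(p, p, cut)
    expect_equal(unclass(rr$children[[1]]), unclass(p))
    expect_equal(unclass(rr$children[[2]]), unclass(p))
    expect_true(all(rr$valid))
  }
  expect_error(crossover(conformation(c(1, 1)), conformation(c(1, 1, 1)), 1),
               "differ in length")
  expect_error(crossover(p, p, 9), "cut must lie")
})

test_that("crossover validity matches decoding every swap", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(6:20, 1)
    p1 <- random_valid_dirs(n)
    p2 <- random_valid_dirs(n)
    for (cut in seq_len(n - 2)) {
      r <- crossover(conformation(p1), conformation(p2), cut)
      c1 <- c(p1[seq_len(cut)], p2[(cut + 1):(n - 1)])
      c2 <- c(p2[seq_len(cut)], p1[(cut + 1):(n - 1)])
      expect_equal(unclass(r$children[[1]]), c1)
      expect_equal(unclass(r$children[[2]]), c2)
      expect_identical(r$valid,
                       c(oracle_valid(oracle_decode(c1)),
                         oracle_valid(oracle_decode(c2))))
    }
  }
})

test_that("pull move matches the independent enumeration oracle", {
  set.seed(33)
  for (rep in 1:40) {
    d <- random_valid_dirs(8)
    space <- oracle_pull_space(d)
    for (mv in space) {
      got <- pull_move(conformation(d), mv$residue, mv$end, mv$target)
      want <- oracle_pull(d, mv$residue, mv$end, mv$target)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_false(is.null(got))
        # compare direction strings: the encoding is translation-invariant,
        # so a moved first residue re-anchors the decoded frame
        expect_equal(unclass(got), oracle_encode(want))
        expect_true(validate_conformation(got)$valid)
      }
    }
  }
})

test_that("a doubly-adjacent pull target reduces to a single relocation", {
  # square-ish loop: residue 3 has a free point adjacent to both neighbours
  set.seed(34)
  found <- 0
  for (rep in 1:50) {
    d <- random_valid_dirs(8)
    coords <- oracle_decode(d)
    for (i in 2:7) {
      for (k in 1:12) {
        t <- coords[i - 1, ] + oracle_basis[k, ]
        occupied <- oracle_key(coords)
        if (paste(t[1], t[2], t[3]) %in% occupied) next
        if (!fcc_is_adjacent(t, coords[i + 1, ])) next
        # adjacent to both neighbours: only residue i moves
        got <- pull_move(conformation(d), i, "tail", t)
        expect_false(is.null(got))
        expected <- coords
        expected[i, ] <- t
        expect_equal(unclass(got), oracle_encode(expected))
        found <- found + 1
      }
    }
  }
  expect_gt(found, 10)
})

test_that("diagonal move needs a free common neighbour", {
  # two adjacent FCC points share exactly 4 common neighbours
  nb1 <- fcc_neighbors(c(0, 0, 0))
  nb2 <- fcc_neighbors(c(1, 1, 0))
  common <- merge(as.data.frame(nb1), as.data.frame(nb2))
  expect_equal(nrow(common), 4L)

  set.seed(35)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    d <- random_valid_dirs(n)
    coords <- oracle_decode(d)
    occupied <- oracle_key(coords)
    for (i in seq_len(n)) {
      # enumerate candidate targets the way the contract defines them
      base <- if (i == 1) coords[2, ] else coords[i - 1, ]
      cands <- 0
      for (k in 1:12) {
        t <- base + oracle_basis[k, ]
        if (paste(t[1], t[2], t[3]) %in% occupied) next
        if (i > 1 && i < n && !fcc_is_adjacent(t, coords[i + 1, ])) next
        cands <- cands + 1
        got <- diagonal_move(conformation(d), i, t)
        expect_false(is.null(got))
        new <- coords
        new[i, ] <- t
        expect_equal(unclass(got), oracle_encode(new))
        expect_true(validate_conformation(got)$valid)
        # reversibility: the inverse move restores the original (the target
        # must be expressed in the re-anchored frame when residue 1 moved)
        t_inv <- if (i == 1) coords[1, ] - t else coords[i, ]
        back <- diagonal_move(got, i, t_inv)
        expect_equal(unclass(back), d)
      }
      if (i > 1 && i < n) expect_lte(cands, 4)
    }
  }
  # occupied or non-adjacent targets are infeasible
  d <- c(1, 1, 1)
  expect_null(diagonal_move(conformation(d), 2, c(0, 0, 0)))
  expect_null(diagonal_move(conformation(d), 2, c(5, 5, 0)))
})

test_that("rotation re-samples a suffix and keeps the prefix", {
  set.seed(36)
  for (rep in 1:30) {
    n <- sample(6:15, 1)
    d <- random_valid_dirs(n)
    s <- sample(seq_len(n - 1), 1)
    out <- rotation(conformation(d), s)
    if (!is.null(out)) {
      expect_true(validate_conformation(out)$valid)
      if (s > 1) expect_equal(unclass(out)[seq_len(s - 1)], d[seq_len(s - 1)])
      expect_equal(unname(decode_conformation(out)[seq_len(s), ]),
                   unname(oracle_decode(d)[seq_len(s), ]))
    }
  }
  expect_error(rotation(conformation(c(1, 1, 1)), 4), "out of range")
})

test_that("exhaustive application returns the enumeration arg-min", {
  set.seed(37)
  bm <- bm_matrix()
  M <- unclass(bm)
  for (rep in 1:15) {
    n <- sample(6:10, 1)
    d <- random_valid_dirs(n)
    res <- random_residues(n)
    got <- exhaustive_apply("pull", conformation(d), res, bm)
    # oracle: every (residue, end, target) triple, scored independently
    energies <- c()
    for (mv in oracle_pull_space(d)) {
      new <- oracle_pull(d, mv$residue, mv$end, mv$target)
      if (!is.null(new)) energies <- c(energies, oracle_energy(new, res, M))
    }
    expect_true(got$feasible)
    expect_equal(got$energy, min(energies))
    expect_equal(got$n_evaluations, length(energies))
    expect_true(validate_conformation(got$conformation)$valid)
    expect_length(unclass(got$conformation), n - 1)
  }
})

test_that("exhaustive diagonal and crossover agree with their oracles", {
  set.seed(38)
  bm <- bm_matrix()
  M <- unclass(bm)
  for (rep in 1:15) {
    n <- sample(6:10, 1)
    d <- random_valid_dirs(n)
    res <- random_residues(n)
    got <- exhaustive_apply("diagonal", conformation(d), res, bm)
    coords <- oracle_decode(d)
    occupied <- oracle_key(coords)
    energies <- c()
    for (i in seq_len(n)) {
      base <- if (i == 1) coords[2, ] else coords[i - 1, ]
      for (k in 1:12) {
        t <- base + oracle_basis[k, ]
        if (paste(t[1], t[2], t[3]) %in% occupied) next
        if (i > 1 && i < n && !fcc_is_adjacent(t, coords[i + 1, ])) next
        new <- coords
        new[i, ] <- t
        if (oracle_conf_ok(new))
          energies <- c(energies, oracle_energy(new, res, M))
      }
    }
    if (length(energies)) {
      expect_true(got$feasible)
      expect_equal(got$energy, min(energies))
      expect_equal(got$n_evaluations, length(energies))
    } else {
      expect_false(got$feasible)
    }

    p2 <- random_valid_dirs(n)
    gotx <- exhaustive_apply("crossover", conformation(d), res, bm,
                             partner = conformation(p2))
    ex <- c()
    for (cut in seq_len(n - 2)) {
      for (child in list(c(d[seq_len(cut)], p2[(cut + 1):(n - 1)]),
                         c(p2[seq_len(cut)], d[(cut + 1):(n - 1)]))) {
        cc <- oracle_decode(child)
        if (oracle_valid(cc)) ex <- c(ex, oracle_energy(cc, res, M))
      }
    }
    if (length(ex)) {
      expect_true(gotx$feasible)
      expect_equal(gotx$energy, min(ex))
      expect_equal(gotx$n_evaluations, length(ex))
    } else {
      expect_false(gotx$feasible)
    }
  }
})

test_that("every operator output is a valid conformation of equal length", {
  set.seed(39)
  bm <- bm_matrix()
  checked <- 0
  for (rep in 1:250) {
    n <- sample(5:18, 1)
    d <- random_valid_dirs(n)
    res <- random_residues(n)
    op <- sample(c("pull", "crossover", "diagonal", "rotation"), 1)
    partner <- if (op == "crossover") conformation(random_valid_dirs(n))
               else NULL
    got <- exhaustive_apply(op, conformation(d), res, bm, partner = partner)
    expect_true(validate_conformation(got$conformation)$valid)
    expect_length(unclass(got$conformation), n - 1)
    checked <- checked + 1
    # random-walk perturbation also preserves validity
    pb <- random_walk_perturb(conformation(d), n_pulls = 3)
    expect_true(validate_conformation(pb)$valid)
    expect_length(unclass(pb), n - 1)
  }
  expect_equal(checked, 250)
})

test_that("exhaustive application is deterministic given the RNG state", {
  bm <- bm_matrix()
  d <- NULL
  set.seed(40)
  d <- random_valid_dirs(12)
  res <- random_residues(12)
  set.seed(41)
  a <- exhaustive_apply("rotation", conformation(d), res, bm)
  set.seed(41)
  b <- exhaustive_apply("rotation", conformation(d), res, bm)
  expect_identical(a, b)
})
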