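# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ paths: plain-R decoding, quadratic all-pairs
# checks, and exhaustive enumeration.

oracle_basis <- matrix(c(
  1, 1, 0, -1, -1, 0, -1, 1, 0, 1, -1, 0,
  0, 1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1,
  1, 0, 1, -1, 0, 1, 1, 0, -1, -1, 0, -1),
  ncol = 3, byrow = TRUE)

oracle_decode <- function(dirs, origin = c(0, 0, 0)) {
  steps <- oracle_basis[dirs, , drop = FALSE]
  cs <- apply(steps, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  coords <- sweep(rbind(c(0, 0, 0), cs), 2, origin, "+")
  dimnames(coords) <- NULL
  coords
}

oracle_key <- function(coords) paste(coords[, 1], coords[, 2], coords[, 3])

# quadratic all-pairs self-avoidance check
oracle_valid <- function(coords) !anyDuplicated(oracle_key(coords))

oracle_adjacent_mat <- function(coords) {
  dx <- abs(outer(coords[, 1], coords[, 1], "-"))
  dy <- abs(outer(coords[, 2], coords[, 2], "-"))
  dz <- abs(outer(coords[, 3], coords[, 3], "-"))
  dx <= 1 & dy <= 1 & dz <= 1 & (dx + dy + dz) == 2
}

# all contact pairs (a < b, b - a > 1) by brute-force double loop
oracle_contacts <- function(coords) {
  adj <- oracle_adjacent_mat(coords)
  n <- nrow(coords)
  out <- NULL
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (adj[a, b]) out <- rbind(out, c(a, b))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

oracle_energy <- function(coords, residues, M) {
  ct <- oracle_contacts(coords)
  if (nrow(ct) == 0) return(0)
  sum(M[cbind(residues[ct[, 1]], residues[ct[, 2]])])
}

# chain bonds + self-avoidance for coordinate-space results
oracle_conf_ok <- function(coords) {
  n <- nrow(coords)
  bonds <- vapply(seq_len(n - 1), function(k) {
    d <- abs(coords[k + 1, ] - coords[k, ])
    all(d <= 1) && sum(d) == 2
  }, logical(1))
  all(bonds) && oracle_valid(coords)
}

random_dirs <- function(n) sample(1:12, n - 1, replace = TRUE)

# rejection-sampled valid conformation, independent of chain_growth_init
random_valid_dirs <- function(n, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    d <- random_dirs(n)
    if (oracle_valid(oracle_decode(d))) return(d)
  }
  stop("could not sample a valid conformation of length ", n)
}

# Independent pull-move construction: relocate residue i to `target`, then
# let each residue on the dragged side step into the position its
# predecessor vacated until adjacency is restored; full validity check.
oracle_pull <- function(dirs, residue, end, target) {
  coords <- oracle_decode(dirs)
  n <- nrow(coords)
  d <- if (end == "tail") 1L else -1L
  i <- residue
  anchor <- i - d
  if (any(apply(coords, 1, function(p) all(p == target)))) return(NULL)
  if (anchor >= 1 && anchor <= n) {
    if (!all(abs(target - coords[anchor, ]) <= 1) ||
        sum(abs(target - coords[anchor, ])) != 2) return(NULL)
  } else {
    if (!all(abs(target - coords[i, ]) <= 1) ||
        sum(abs(target - coords[i, ])) != 2) return(NULL)
  }
  new <- coords
  new[i, ] <- target
  prev <- coords[i, ]
  j <- i + d
  while (j >= 1 && j <= n) {
    dd <- abs(new[j - d, ] - coords[j, ])
    if (all(dd <= 1) && sum(dd) == 2) break
    tmp <- coords[j, ]
    new[j, ] <- prev
    prev <- tmp
    j <- j + d
  }
  if (!oracle_conf_ok(new)) return(NULL)
  new
}

# every (residue, end, free neighbour target) triple
oracle_pull_space <- function(dirs) {
  coords <- oracle_decode(dirs)
  n <- nrow(coords)
  occupied <- oracle_key(coords)
  out <- list()
  for (i in seq_len(n)) {
    for (end in c("tail", "head")) {
      d <- if (end == "tail") 1L else -1L
      anchor <- i - d
      base <- if (anchor >= 1 && anchor <= n) coords[anchor, ] else coords[i, ]
      for (k in 1:12) {
        t <- base + oracle_basis[k, ]
        if (paste(t[1], t[2], t[3]) %in% occupied) next
        out[[length(out) + 1]] <- list(residue = i, end = end, target = t)
      }
    }
  }
  out
}

# re-encode coordinates as direction indices (identity check helper)
oracle_encode <- function(coords) {
  n <- nrow(coords)
  vapply(seq_len(n - 1), function(k) {
    step <- coords[k + 1, ] - coords[k, ]
    hit <- which(oracle_basis[, 1] == step[1] & oracle_basis[, 2] == step[2] &
                 oracle_basis[, 3] == step[3])
    if (length(hit) != 1) stop("step is not a basis vector")
    hit
  }, integer(1))
}

random_residues <- function(n) sample(amino_acids(), n, replace = TRUE)

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation_matrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
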