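# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

# Brute-force graph-automorphism orbits: enumerate all element-preserving
# atom permutations that map the bond set onto itself (feasible for the
# small fixtures), then read off the orbit partition.
automorphism_orbits <- function(mol) {
  n <- length(mol$elements)
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, "i"]; j <- mol$bonds[k, "j"]
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  groups <- split(seq_len(n), mol$elements)
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  group_perms <- lapply(groups, perms_of)
  same_orbit <- diag(TRUE, n)
  add_perm <- function(p) {
    if (all(adj[p, p] == adj)) {
      for (i in seq_len(n)) same_orbit[i, p[i]] <<- TRUE
    }
  }
  idx <- lapply(group_perms, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    p <- integer(n)
    for (g in seq_along(groups)) {
      p[groups[[g]]] <- group_perms[[g]][[grid[r, g]]]
    }
    add_perm(p)
  }
  # transitive closure of the symmetric orbit relation
  repeat {
    nxt <- (same_orbit %*% same_orbit) > 0
    if (identical(nxt, same_orbit)) break
    same_orbit <- nxt
  }
  match(apply(same_orbit, 1L, function(row) paste(which(row), collapse = ",")),
        unique(apply(same_orbit, 1L, function(row)
          paste(which(row), collapse = ","))))
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, paste, collapse = ",") %in%
          tapply(seq_along(b), b, paste, collapse = ",")) &&
    length(unique(a)) == length(unique(b))
}

# Direct equality-constrained linear least squares min ||A q - v||,
# sum(q) = total, by null-space elimination (independent of the package's
# KKT solve).
constrained_ls_oracle <- function(a, v, total) {
  n <- ncol(a)
  # q = q0 + Z u with q0 = total/n * 1, Z an orthonormal basis of 1-perp
  q0 <- rep(total / n, n)
  z <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  az <- a %*% z
  u <- qr.coef(qr(az), v - a %*% q0)
  drop(q0 + z %*% u)
}

# random proper rotation matrix
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rebuild a conformer with transformed coordinates
transform_conformer <- function(conf, rot = diag(3), shift = c(0, 0, 0)) {
  conformer(conf$molecule,
            sweep(conf$coordinates %*% t(rot), 2L, shift, "+"))
}

# noiseless gas-phase grids for a fixture
fixture_gas_grids <- function(fx) {
  lapply(fx$conformers, synthesize_esp, model = fx$model, phase = "gas")
}
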