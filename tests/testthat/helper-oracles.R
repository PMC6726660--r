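# Independent oracles, kept deliberately separate from the package's own
# implementations: a Gotoh dynamic-programming aligner, exhaustive parsimony
# enumeration, and a brute-force rank-sum permutation test.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# global affine-gap alignment score; a gap of length L costs open + L * ext
nw_oracle_score <- function(a, b, open = 10, ext = 1, mat = .blosum62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive minimum-change parsimony for a binary trait: enumerate every
# internal labeling, count changes over edges
enum_parsimony <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- integer(ntip + nnode)
  states[seq_len(ntip)] <- tip_states[tree$tip.label]
  best <- Inf
  best_sets <- vector("list", ntip + nnode)
  for (v in seq_len(ntip + nnode)) best_sets[[v]] <- integer(0)
  for (code in 0:(2^nnode - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(nnode)]
    states[(ntip + 1):(ntip + nnode)] <- lab
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    if (changes < best) {
      best <- changes
      for (v in seq_len(ntip + nnode)) best_sets[[v]] <- integer(0)
    }
    if (changes == best) {
      for (v in seq_len(ntip + nnode)) {
        best_sets[[v]] <- union(best_sets[[v]], states[v])
      }
    }
  }
  sets <- vapply(best_sets, function(s) paste(sort(s), collapse = ""), "")
  list(changes = best, state_sets = sets)
}

# brute-force permutation p-value for the Mann-Whitney U of x vs y, counting
# x>y pairs directly (ties count one half)
mw_oracle <- function(x, y, alternative = "two.sided") {
  u_of <- function(xx, yy) {
    sum(vapply(xx, function(v) sum(v > yy) + 0.5 * sum(v == yy), 0))
  }
  n1 <- length(x)
  pooled <- c(x, y)
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# small record helpers
rec1 <- function(id, residues) cx_records(id = id, residues = residues)

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
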