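# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: shortest paths come from adjacency-matrix powers, matrix
# products and similarity entries from explicit loops over edge sets.

# Capped shortest-path matrix by the min-power definition:
# SPM(i,j) = min{ k in 1..r : (AM^k)(i,j) != 0 }, else 0; diagonal 0.
oracle_spm <- function(AM, r) {
  n <- nrow(AM)
  res <- matrix(0L, n, n)
  P <- diag(n)
  for (k in seq_len(r)) {
    P <- P %*% AM
    res[res == 0L & P != 0] <- k
  }
  diag(res) <- 0L
  res
}

# Straight-line trace of the whole scoring chain (distances -> closeness
# weights -> association degrees -> disease x lncRNA block -> similarity
# weighting), all with explicit loops.
oracle_pipeline <- function(AM, D, M, L, r, fsd = NULL, fsl = NULL) {
  n <- D + M + L
  spm <- oracle_spm(AM, r)
  dcc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dcc[i, j] <- if (i == j) r / (r + 1)
        else if (spm[i, j] > 0) 1 - spm[i, j] / (r + 1)
        else 0
    }
  }
  ad <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ad[i, j] <- (sum(dcc[i, ]) + sum(dcc[, j])) / n
    }
  }
  c13 <- ad[seq_len(D), D + M + seq_len(L), drop = FALSE]
  if (is.null(fsd)) return(c13)
  fad <- matrix(0, D, L)
  for (i in seq_len(D)) {
    for (j in seq_len(L)) {
      s <- 0
      for (a in seq_len(D)) {
        for (b in seq_len(L)) {
          s <- s + fsd[i, a] * c13[a, b] * fsl[b, j]
        }
      }
      fad[i, j] <- s
    }
  }
  fad
}

# Pairwise similarity from raw edge sets by a double loop.
oracle_similarity <- function(edges, contributions, entities,
                              convention = "quotient_inside_exp") {
  nb <- lapply(entities, function(e) unique(edges$right[edges$left == e]))
  n <- length(entities)
  sim <- matrix(0, n, n, dimnames = list(entities, entities))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(nb[[i]], nb[[j]])
      S <- sum(contributions[shared])
      Q <- length(nb[[i]]) + length(nb[[j]]) - length(shared)
      sim[i, j] <- if (convention == "quotient_inside_exp") {
        if (Q > 0) exp(S / Q) else 1
      } else {
        if (Q > 0) exp(S) / Q else 1
      }
    }
  }
  sim
}

# Random intersected table pair over a shared miRNA space; retries until
# both tables are non-empty on a common miRNA set.
random_tables <- function(D, M, L, p) {
  repeat {
    dm <- matrix(stats::runif(D * M) < p, D, M)
    ml <- matrix(stats::runif(M * L) < p, M, L)
    shared <- which(colSums(dm) > 0 & rowSums(ml) > 0)
    if (length(shared) == 0L) next
    dmi <- which(dm[, shared, drop = FALSE], arr.ind = TRUE)
    mli <- which(ml[shared, , drop = FALSE], arr.ind = TRUE)
    ds <- sprintf("d%02d", seq_len(D)); ms <- sprintf("m%02d", shared)
    ls <- sprintf("l%02d", seq_len(L))
    return(list(
      dm = assoc_table(data.frame(left = ds[dmi[, 1]], right = ms[dmi[, 2]]),
                       "disease", "miRNA"),
      ml = assoc_table(data.frame(left = ms[mli[, 1]], right = ls[mli[, 2]]),
                       "miRNA", "lncRNA")
    ))
  }
}

# Write an assoc_table-shaped TSV fixture to a temp file.
write_fixture_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
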