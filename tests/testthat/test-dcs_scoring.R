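path3 <- function() {
  build_network(
    assoc_table(data.frame(left = "d1", right = "m1"), "disease", "miRNA"),
    assoc_table(data.frame(left = "m1", right = "l1"), "miRNA", "lncRNA"))
}

test_that("distance correlation coefficients map distances to closeness", {
  expect_equal(distance_correlation_coefficient(1, 6), 6 / 7)
  expect_equal(distance_correlation_coefficient(6, 6), 1 / 7)
  expect_equal(distance_correlation_coefficient(0, 6), 0)
  expect_equal(distance_correlation_coefficient(0:4, 4),
               c(0, 4 / 5, 3 / 5, 2 / 5, 1 / 5))
  expect_error(distance_correlation_coefficient(7, 6), "\\[0, r\\]")
})

test_that("the DCCM has the stated diagonal, codomain, and symmetry", {
  # empty graph: diagonal r/(r+1), zeros elsewhere
  net0 <- build_network(
    assoc_table(data.frame(left = "d1", right = "m1"), "disease", "miRNA"),
    assoc_table(data.frame(left = "m1", right = "l1"), "miRNA", "lncRNA"),
    diseases = c("d1", "d2"))
  net0$AM[] <- 0L
  d0 <- build_dccm(shortest_path_matrix(net0, 3))
  expect_equal(unname(diag(d0$values)), rep(3 / 4, 4))
  expect_equal(sum(d0$values) - sum(diag(d0$values)), 0)

  # hand-evaluated 3-node path at r = 2
  dcc <- build_dccm(shortest_path_matrix(path3(), 2))
  expect_equal(dcc$values["d1", "m1"], 2 / 3)
  expect_equal(dcc$values["m1", "l1"], 2 / 3)
  expect_equal(dcc$values["d1", "l1"], 1 / 3)
  expect_equal(unname(diag(dcc$values)), rep(2 / 3, 3))

  set.seed(61)
  for (k in 1:10) {
    tabs <- random_tables(5, 4, 6, 0.3)
    r <- sample(2:6, 1)
    v <- build_dccm(shortest_path_matrix(build_network(tabs$dm, tabs$ml), r))$values
    expect_identical(as.vector(v), as.vector(t(v)))
    allowed <- c(0, ((r + 1) - seq_len(r)) / (r + 1), r / (r + 1))
    expect_true(all(v %in% allowed))
    expect_true(all(v >= 0 & v <= r / (r + 1)))
  }
})

test_that("association degrees are row/column-sum averages", {
  # full hand trace of the 3-node path: rowsums (5/3, 2, 5/3), N = 3
  ad <- association_degree(build_dccm(shortest_path_matrix(path3(), 2)))
  expect_equal(ad["d1", "l1"], 10 / 9, tolerance = 1e-12)
  expect_identical(as.vector(ad), as.vector(t(ad)))

  # diagonal-only DCCM: every entry is 2r/((r+1)N)
  net0 <- path3(); net0$AM[] <- 0L
  ad0 <- association_degree(build_dccm(shortest_path_matrix(net0, 5)))
  expect_equal(unname(ad0), matrix(2 * 5 / (6 * 3), 3, 3))
})

test_that("the prediction block is the disease-by-lncRNA slice", {
  net <- path3()
  ad <- association_degree(build_dccm(shortest_path_matrix(net, 2)))
  c13 <- extract_c13(ad, net)
  expect_equal(dim(c13), c(1L, 1L))
  expect_equal(c13["d1", "l1"], 10 / 9, tolerance = 1e-12)

  set.seed(67)
  tabs <- random_tables(4, 4, 5, 0.4)
  net2 <- build_network(tabs$dm, tabs$ml)
  ad2 <- association_degree(build_dccm(shortest_path_matrix(net2, 4)))
  c13b <- extract_c13(ad2, net2)
  sizes <- block_sizes(net2)
  for (i in seq_len(sizes[["D"]])) {
    for (j in seq_len(sizes[["L"]])) {
      expect_identical(c13b[i, j], ad2[i, sizes[["D"]] + sizes[["M"]] + j])
    }
  }
  expect_error(extract_c13(ad2[-1, -1], net2), "does not match")
})

test_that("final scores apply the similarity weighting or pass through", {
  set.seed(71)
  c13 <- matrix(runif(20), 4, 5,
                dimnames = list(paste0("d", 1:4), paste0("l", 1:5)))
  id_d <- diag(4); dimnames(id_d) <- list(rownames(c13), rownames(c13))
  id_l <- diag(5); dimnames(id_l) <- list(colnames(c13), colnames(c13))
  expect_identical(final_scores(c13, id_d, id_l), c13)
  expect_identical(final_scores(c13, use_similarity = FALSE), c13)

  # triple product against an element-wise loop oracle
  fsd <- matrix(runif(16, 0.5, 2), 4, 4,
                dimnames = list(rownames(c13), rownames(c13)))
  fsl <- matrix(runif(25, 0.5, 2), 5, 5,
                dimnames = list(colnames(c13), colnames(c13)))
  got <- final_scores(c13, fsd, fsl)
  want <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) {
    for (a in 1:4) for (b in 1:5) {
      want[i, j] <- want[i, j] + fsd[i, a] * c13[a, b] * fsl[b, j]
    }
  }
  expect_equal(unname(got), want, tolerance = 1e-10)

  # misaligned names must error, never silently reorder
  bad <- fsd[c(2, 1, 3, 4), c(2, 1, 3, 4)]
  expect_error(final_scores(c13, bad, fsl), "name order")
})

test_that("scores are invariant in rank under positive similarity rescaling", {
  set.seed(73)
  tabs <- random_tables(5, 4, 6, 0.35)
  res <- dcs_score(tabs$dm, tabs$ml, r = 4)
  scaled <- final_scores(res$c13, 3.7 * res$fsd, res$fsl)
  expect_equal(unname(scaled), unname(3.7 * res$fad), tolerance = 1e-10)
  expect_equal(order(scaled), order(res$fad))
})

test_that("the full pipeline matches the straight-line brute-force trace", {
  set.seed(79)
  for (k in 1:8) {
    tabs <- random_tables(sample(2:4, 1), sample(2:4, 1), sample(2:4, 1), 0.4)
    net <- build_network(tabs$dm, tabs$ml)
    sizes <- block_sizes(net)
    r <- sample(2:6, 1)
    res <- dcs_score(tabs$dm, tabs$ml, r = r)
    fsd_o <- oracle_similarity(tabs$dm$edges, mirna_contribution(tabs$dm, 10),
                               net$diseases)
    ml_flip <- data.frame(left = tabs$ml$edges$right,
                          right = tabs$ml$edges$left)
    fsl_o <- oracle_similarity(ml_flip, mirna_contribution(tabs$ml, 2),
                               net$lncrnas)
    want <- oracle_pipeline(net$AM, sizes[["D"]], sizes[["M"]], sizes[["L"]],
                            r, fsd_o, fsl_o)
    expect_equal(unname(res$fad), want, tolerance = 1e-10)
    expect_equal(unname(res$c13),
                 oracle_pipeline(net$AM, sizes[["D"]], sizes[["M"]],
                                 sizes[["L"]], r),
                 tolerance = 1e-10)
  }
})

test_that("adding an edge never decreases any association degree", {
  set.seed(83)
  for (k in 1:6) {
    tabs <- random_tables(4, 4, 5, 0.3)
    net <- build_network(tabs$dm, tabs$ml)
    ad <- association_degree(build_dccm(shortest_path_matrix(net, 4)))
    free <- which(net$AM[net$diseases, net$mirnas, drop = FALSE] == 0L,
                  arr.ind = TRUE)
    if (nrow(free) == 0L) next
    pick <- free[sample(nrow(free), 1), ]
    net2 <- net
    di <- net$diseases[pick[1]]; mi <- net$mirnas[pick[2]]
    net2$AM[di, mi] <- net2$AM[mi, di] <- 1L
    ad2 <- association_degree(build_dccm(shortest_path_matrix(net2, 4)))
    expect_true(all(ad2 >= ad - 1e-12))
  }
})
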