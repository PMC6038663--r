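#' Distance correlation coefficient
#'
#' Maps a capped shortest-path distance to a closeness weight in
#' `[0, r/(r+1)]`: distance k gives `1 - k/(r+1)`, and 0 (no relation
#' within the radius) gives 0.  Vectorized.
#'
#' @param spm_entry integer distance(s) in `0:r`.
#' @param r positive integer radius.
#' @return Numeric weight(s).
#' @export
distance_correlation_coefficient <- function(spm_entry, r) {
  r <- as.integer(r)
  if (r < 1L) stop("radius r must be a positive integer")
  if (any(spm_entry < 0) || any(spm_entry > r)) {
    stop("spm entries must lie in [0, r]")
  }
  # algebraically 1 - k/(r+1); this form makes the k = 1 weight equal
  # the diagonal value r/(r+1) to the last bit
  ifelse(spm_entry > 0, ((r + 1) - spm_entry) / (r + 1), 0)
}

#' Distance correlation coefficient matrix (DCCM)
#'
#' Entrywise closeness weights of the capped shortest-path matrix:
#' off-diagonal entries are `1 - SPM(i,j)/(r+1)` for nodes in each
#' other's distance correlation set and 0 otherwise; the diagonal is
#' `r/(r+1)`.
#'
#' @param spm an `spm_matrix`.
#' @return Object of class `dcc_matrix`: list with `values` (symmetric
#'   numeric matrix) and `radius`.
#' @export
build_dccm <- function(spm) {
  r <- spm$radius
  v <- distance_correlation_coefficient(spm$values, r)
  diag(v) <- r / (r + 1)
  dimnames(v) <- dimnames(spm$values)
  structure(list(values = v, radius = r), class = "dcc_matrix")
}

#' Association degree matrix
#'
#' The association degree of a node pair averages how strongly each
#' member is embedded in the network: `AD(i,j) = (rowsum_i(DCCM) +
#' colsum_j(DCCM)) / N` with `N = D + M + L`.  Since the DCCM is
#' symmetric, AD is symmetric.
#'
#' @param dccm a `dcc_matrix`.
#' @return Symmetric numeric N x N matrix with node names as dimnames.
#' @export
association_degree <- function(dccm) {
  v <- dccm$values
  n <- nrow(v)
  ad <- outer(rowSums(v), colSums(v), "+") / n
  dimnames(ad) <- dimnames(v)
  ad
}

#' Extract the disease-by-lncRNA prediction block
#'
#' Partitioning the association degree matrix by the network's three
#' node blocks, the disease-rows by lncRNA-columns block is the raw
#' prediction matrix.
#'
#' @param ad association degree matrix from [association_degree()].
#' @param net the `tripartite_network` the matrix was computed on.
#' @return D x L numeric matrix with disease row names and lncRNA column
#'   names.
#' @export
extract_c13 <- function(ad, net) {
  sizes <- block_sizes(net)
  n <- sum(sizes)
  if (!identical(dim(ad), c(n, n))) {
    stop("association degree matrix does not match the network size")
  }
  if (sizes[["D"]] == 0L || sizes[["L"]] == 0L) {
    stop("network has no ", if (sizes[["D"]] == 0L) "diseases" else "lncRNAs")
  }
  rows <- seq_len(sizes[["D"]])
  cols <- sizes[["D"]] + sizes[["M"]] + seq_len(sizes[["L"]])
  c13 <- ad[rows, cols, drop = FALSE]
  dimnames(c13) <- list(net$diseases, net$lncrnas)
  c13
}

#' Final association scores
#'
#' Optionally weights the raw prediction block by the two functional
#' similarity matrices: `FAD = FSD %*% C13 %*% FSL`.  Row i / column j
#' is the score that lncRNA j is related to disease i; scores are
#' rankings, not probabilities.  Name order of the similarity matrices
#' must match the prediction block exactly -- mismatches raise an error
#' rather than being silently reordered.
#'
#' @param c13 D x L prediction block from [extract_c13()].
#' @param fsd D x D disease similarity matrix (rows/cols in c13's row
#'   order).
#' @param fsl L x L lncRNA similarity matrix (rows/cols in c13's column
#'   order).
#' @param use_similarity when `FALSE`, returns `c13` unchanged (the
#'   similarity-free ablation arm).
#' @return D x L numeric score matrix with the same dimnames as `c13`.
#' @export
final_scores <- function(c13, fsd = NULL, fsl = NULL, use_similarity = TRUE) {
  if (!use_similarity) return(c13)
  if (is.null(fsd) || is.null(fsl)) {
    stop("fsd and fsl are required when use_similarity = TRUE")
  }
  if (!identical(rownames(fsd), rownames(c13)) ||
      !identical(colnames(fsd), rownames(c13))) {
    stop("disease name order of fsd does not match c13")
  }
  if (!identical(rownames(fsl), colnames(c13)) ||
      !identical(colnames(fsl), colnames(c13))) {
    stop("lncRNA name order of fsl does not match c13")
  }
  fad <- fsd %*% c13 %*% fsl
  dimnames(fad) <- dimnames(c13)
  fad
}

#' Full scoring pipeline
#'
#' Runs the complete method on raw association tables: intersect the
#' miRNA spaces, compute functional similarities on the full
#' (pre-intersection) tables, build the tripartite network, derive
#' capped shortest paths, distance correlation coefficients, association
#' degrees, the disease-by-lncRNA block, and the final score matrix.
#'
#' @param dm disease--miRNA `assoc_table`.
#' @param ml miRNA--lncRNA `assoc_table`.
#' @param r positive integer radius (default 6).
#' @param use_similarity weight by functional similarity (default TRUE).
#' @param convention similarity grouping convention, see
#'   [functional_similarity()].
#' @param drop_isolated drop diseases/lncRNAs left without edges by the
#'   miRNA intersection (default keeps them as isolated nodes so matrix
#'   dimensions reflect the raw tables).
#' @return List with `network`, `spm`, `fsd`, `fsl`, `c13`, `fad`,
#'   `isolated` (names dropped or kept isolated) and the parameters.
#' @export
dcs_score <- function(dm, ml, r = 6L, use_similarity = TRUE,
                      convention = c("quotient_inside_exp",
                                     "exp_over_denominator"),
                      drop_isolated = FALSE) {
  convention <- match.arg(convention)
  inter <- intersect_mirna_space(dm, ml)
  diseases <- if (drop_isolated) entity_names(inter$t1, "left")
              else entity_names(dm, "left")
  lncrnas <- if (drop_isolated) entity_names(inter$t2, "right")
             else entity_names(ml, "right")
  net <- build_network(inter$t1, inter$t2,
                       diseases = diseases, lncrnas = lncrnas)
  fsd <- fsl <- NULL
  if (use_similarity) {
    # similarities are defined on the full bipartite tables, before the
    # miRNA intersection restricts the network
    fsd <- functional_similarity(dm, side = "disease",
                                 convention = convention,
                                 entities = diseases)
    fsl <- functional_similarity(ml, side = "lncRNA",
                                 convention = convention,
                                 entities = lncrnas)
  }
  spm <- shortest_path_matrix(net, r)
  c13 <- extract_c13(association_degree(build_dccm(spm)), net)
  fad <- final_scores(c13, fsd, fsl, use_similarity = use_similarity)
  list(network = net, spm = spm, fsd = fsd, fsl = fsl, c13 = c13,
       fad = fad,
       isolated = list(diseases = inter$isolated_left,
                       lncrnas = inter$isolated_right),
       r = spm$radius, use_similarity = use_similarity,
       convention = convention, drop_isolated = drop_isolated)
}
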