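#' Build the tripartite disease--miRNA--lncRNA network
#'
#' Stacks the two intersected association tables into one undirected
#' graph whose node registry is ordered in three fixed blocks: diseases,
#' then miRNAs, then lncRNAs.  The graph is bipartite between
#' `{diseases, lncRNAs}` and `{miRNAs}` -- there are no same-layer edges
#' and no direct disease--lncRNA edges; diseases and lncRNAs are linked
#' only through shared miRNA neighbors.
#'
#' @param dm disease--miRNA `assoc_table` (miRNAs on the right).
#' @param ml miRNA--lncRNA `assoc_table` (miRNAs on the left).
#' @param diseases,lncrnas,mirnas optional registries fixing block
#'   content and order (must cover all names present in the edges; extra
#'   names yield isolated nodes).  Default: sorted names observed in the
#'   tables; for miRNAs the two tables must then agree on the set, i.e.
#'   have been intersected with [intersect_mirna_space()] first.
#' @return Object of class `tripartite_network`: list with `diseases`,
#'   `mirnas`, `lncrnas` (ordered name vectors) and `AM`, the symmetric
#'   0/1 adjacency matrix of size `D + M + L` with zero diagonal.
#' @export
build_network <- function(dm, ml, diseases = NULL, lncrnas = NULL,
                          mirnas = NULL) {
  if (dm$right_layer != "miRNA" || ml$left_layer != "miRNA") {
    stop("expected miRNAs on the right of dm and the left of ml")
  }
  m1 <- unique(dm$edges$right)
  m2 <- unique(ml$edges$left)
  if (is.null(mirnas)) {
    if (!setequal(m1, m2)) {
      stop("tables are not intersected on a shared miRNA set; ",
           "call intersect_mirna_space() first")
    }
    mirnas <- sort(m1)
  } else if (!all(m1 %in% mirnas) || !all(m2 %in% mirnas)) {
    stop("tables reference miRNAs outside the given registry")
  }
  if (is.null(diseases)) diseases <- entity_names(dm, "left")
  if (is.null(lncrnas)) lncrnas <- entity_names(ml, "right")
  if (!all(dm$edges$left %in% diseases)) stop("disease registry incomplete")
  if (!all(ml$edges$right %in% lncrnas)) stop("lncRNA registry incomplete")
  nodes <- c(diseases, mirnas, lncrnas)
  if (anyDuplicated(nodes)) {
    stop("entity names collide across layers: ",
         paste(utils::head(nodes[duplicated(nodes)], 3), collapse = ", "))
  }
  n <- length(nodes)
  AM <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  AM[cbind(dm$edges$left, dm$edges$right)] <- 1L
  AM[cbind(ml$edges$left, ml$edges$right)] <- 1L
  AM <- pmax(AM, t(AM))
  structure(
    list(diseases = diseases, mirnas = mirnas, lncrnas = lncrnas, AM = AM),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(
    "tripartite_network: D=%d diseases, M=%d miRNAs, L=%d lncRNAs, %d edges\n",
    length(x$diseases), length(x$mirnas), length(x$lncrnas), sum(x$AM) / 2
  ))
  invisible(x)
}

#' Block sizes of a tripartite network
#' @param net a `tripartite_network`.
#' @return Named integer vector `c(D =, M =, L =)`.
#' @export
block_sizes <- function(net) {
  c(D = length(net$diseases), M = length(net$mirnas),
    L = length(net$lncrnas))
}

#' Radius-capped shortest-path matrix
#'
#' Entry (i, j) is the graph distance between nodes i and j when that
#' distance is between 1 and `r`, and 0 otherwise (unreachable, or
#' farther than `r`; the diagonal is 0 by convention).  Equivalently it
#' is the smallest power `k <= r` at which the adjacency-matrix power
#' `AM^k` has a nonzero (i, j) entry -- the implementation uses
#' breadth-first search but must match that matrix-power definition
#' entrywise.  Consumers must treat 0 as "no relation within radius r",
#' never as distance zero.
#'
#' @param net a `tripartite_network`.
#' @param r positive integer radius cap.
#' @return Object of class `spm_matrix`: list with `values` (integer
#'   matrix, entries in `0:r`) and `radius`.
#' @export
shortest_path_matrix <- function(net, r = 6L) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L) {
    stop("radius r must be a positive integer")
  }
  g <- igraph::graph_from_adjacency_matrix(net$AM, mode = "undirected")
  d <- igraph::distances(g)
  d[!is.finite(d) | d > r] <- 0
  diag(d) <- 0
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(net$AM)
  structure(list(values = d, radius = r), class = "spm_matrix")
}

#' Distance correlation set of a node
#'
#' The set of nodes at capped distance 1..r from the center: every node
#' the shortest-path matrix records a nonzero distance to.
#'
#' @param spm an `spm_matrix`.
#' @param i node index or node name.
#' @return Object of class `dcs_set`: list with `center` (index) and
#'   `members` (sorted integer indices; node names retained in
#'   `member_names`).
#' @export
distance_correlation_set <- function(spm, i) {
  n <- nrow(spm$values)
  if (is.character(i)) i <- match(i, rownames(spm$values))
  if (is.na(i) || i < 1L || i > n) stop("node index out of bounds")
  members <- which(spm$values[i, ] > 0L)
  members <- sort(setdiff(members, i))
  structure(
    list(center = as.integer(i), members = as.integer(members),
         member_names = rownames(spm$values)[members]),
    class = "dcs_set"
  )
}
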