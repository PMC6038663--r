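#' miRNA contribution values
#'
#' In a bipartite association table, a miRNA linked to many partners
#' carries less information about any one of them than a rarely observed
#' miRNA.  The contribution value captures this as the negative log of
#' the miRNA's edge fraction: `-log_base(deg(m) / |E|)`, where `deg(m)`
#' is the number of edges incident to miRNA `m` and `|E|` the table's
#' total edge count.  The disease side conventionally uses base 10, the
#' lncRNA side base 2.
#'
#' @param table a non-empty `assoc_table` with a miRNA layer.
#' @param log_base 10 or 2.
#' @return Named numeric vector of contribution values (one per observed
#'   miRNA, all `>= 0`), with attributes `log_base` and `total_edges`.
#' @export
mirna_contribution <- function(table, log_base = 10) {
  if (!log_base %in% c(10, 2)) stop("log_base must be 10 or 2")
  side <- .layer_side(table, "miRNA")
  if (is.null(side)) stop("table has no miRNA layer")
  if (n_edges(table) == 0L) stop("empty association table")
  deg <- base::table(factor(table$edges[[side]]))
  total <- sum(deg)
  vals <- -log(as.numeric(deg) / total, base = log_base)
  names(vals) <- names(deg)
  attr(vals, "log_base") <- log_base
  attr(vals, "total_edges") <- total
  vals
}

#' miRNA-based functional similarity matrix
#'
#' Similarity between two diseases (or two lncRNAs) is driven by the
#' miRNAs they share: with `S` the summed contribution of the shared
#' miRNA neighborhood and `Q = |N(i)| + |N(j)| - |N(i) inter N(j)|` the
#' size of the joint neighborhood, the default convention scores the
#' pair as `exp(S / Q)`.  Pairs with disjoint neighborhoods get
#' `exp(0) = 1`.  The diagonal is computed by the same literal formula
#' (`exp(sum C(N(i)) / |N(i)|)`), not forced to a maximum.  The grouping
#' of the published formula is ambiguous, so the alternative reading
#' `exp(S) / Q` is selectable via `convention`.
#'
#' @param table `assoc_table` pairing the entities with miRNAs.
#' @param contributions output of [mirna_contribution()] on `table`
#'   (computed if omitted, with base 10 for diseases and base 2 for
#'   lncRNAs).
#' @param side `"disease"` or `"lncRNA"`: which layer of `table` the
#'   matrix is over.
#' @param convention `"quotient_inside_exp"` (default, `exp(S/Q)`) or
#'   `"exp_over_denominator"` (`exp(S)/Q`).
#' @param entities optional character vector fixing the row/column order
#'   (and admitting entities with no edges); defaults to the sorted
#'   observed names.
#' @return Symmetric numeric matrix with entity names as dimnames and
#'   attribute `side`.
#' @export
functional_similarity <- function(table, contributions = NULL,
                                  side = c("disease", "lncRNA"),
                                  convention = c("quotient_inside_exp",
                                                 "exp_over_denominator"),
                                  entities = NULL) {
  side <- match.arg(side)
  convention <- match.arg(convention)
  col <- .layer_side(table, side)
  mcol <- .layer_side(table, "miRNA")
  if (is.null(col) || is.null(mcol)) {
    stop("table must pair ", side, "s with miRNAs")
  }
  if (is.null(contributions)) {
    contributions <- mirna_contribution(table,
                                        if (side == "disease") 10 else 2)
  }
  mirnas <- unique(table$edges[[mcol]])
  missing <- setdiff(mirnas, names(contributions))
  if (length(missing)) {
    stop("no contribution value for miRNA(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  if (is.null(entities)) entities <- entity_names(table, col)
  # incidence B: entities x miRNAs; shared-neighborhood sums are then
  # two rank-|mirnas| products instead of an entity-pair double loop
  B <- matrix(0, length(entities), length(mirnas),
              dimnames = list(entities, mirnas))
  B[cbind(table$edges[[col]], table$edges[[mcol]])] <- 1
  S <- B %*% (t(B) * contributions[mirnas])     # sum C over N(i) inter N(j)
  shared <- B %*% t(B)
  deg <- rowSums(B)
  Q <- outer(deg, deg, "+") - shared
  if (any(deg == 0)) {
    warning("entities with empty miRNA neighborhood: ",
            paste(utils::head(entities[deg == 0], 3), collapse = ", "))
  }
  sim <- if (convention == "quotient_inside_exp") {
    exp(ifelse(Q > 0, S / Q, 0))
  } else {
    ifelse(Q > 0, exp(S) / Q, 1)
  }
  sim <- (sim + t(sim)) / 2          # guard symmetry against fp noise
  dimnames(sim) <- list(entities, entities)
  attr(sim, "side") <- side
  attr(sim, "convention") <- convention
  sim
}
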