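#' Association tables between two entity layers
#'
#' An association table is a deduplicated bipartite edge list between two
#' named layers (`"disease"`, `"miRNA"` or `"lncRNA"`).  It is the common
#' currency of the package: the disease--miRNA table, the miRNA--lncRNA
#' table and the gold-standard lncRNA--disease table are all association
#' tables.
#'
#' @param edges data.frame with character columns `left` and `right`.
#' @param left_layer,right_layer layer labels; must differ.
#' @param provenance free-text source tag carried through unchanged.
#' @return An object of class `assoc_table`: a list with fields
#'   `left_layer`, `right_layer`, `edges` (deduplicated data.frame) and
#'   `provenance`.
#' @export
assoc_table <- function(edges, left_layer, right_layer, provenance = "") {
  stopifnot(is.data.frame(edges), all(c("left", "right") %in% names(edges)))
  left_layer <- match.arg(left_layer, .layers)
  right_layer <- match.arg(right_layer, .layers)
  if (left_layer == right_layer) {
    stop("left and right layers must differ, both are '", left_layer, "'")
  }
  edges <- data.frame(
    left = as.character(edges$left),
    right = as.character(edges$right),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(edges$left)) || any(!nzchar(edges$right))) {
    stop("association table contains empty entity names")
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(
    list(left_layer = left_layer, right_layer = right_layer,
         edges = edges, provenance = provenance),
    class = "assoc_table"
  )
}

.layers <- c("disease", "miRNA", "lncRNA")

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf(
    "assoc_table: %s--%s, %d edges, %d x %d entities%s\n",
    x$left_layer, x$right_layer, nrow(x$edges),
    length(unique(x$edges$left)), length(unique(x$edges$right)),
    if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""
  ))
  invisible(x)
}

#' Number of edges in an association table
#' @param table an `assoc_table`.
#' @return Integer edge count.
#' @export
n_edges <- function(table) nrow(table$edges)

#' Distinct entity names of one side of an association table
#' @param table an `assoc_table`.
#' @param side `"left"` or `"right"`.
#' @return Sorted character vector of distinct names.
#' @export
entity_names <- function(table, side = c("left", "right")) {
  side <- match.arg(side)
  sort(unique(table$edges[[side]]))
}

# Column of the table holding the given layer, or NULL.
.layer_side <- function(table, layer) {
  if (table$left_layer == layer) "left"
  else if (table$right_layer == layer) "right"
  else NULL
}

#' miRNA name normalization policy
#'
#' Controls how raw miRNA identifiers are folded together so that locus
#' copies producing the same mature miRNA collapse to one name.
#'
#' @param lowercase casefold all names (`hsa-miR-21` and `HSA-MIR-21`
#'   become `hsa-mir-21`).
#' @param merge_locus_suffix collapse a trailing `-1`/`-2`/`-3` locus-copy
#'   suffix, but only when the remainder still ends in a digit-bearing
#'   miR identifier (so `hsa-mir-121-1` folds to `hsa-mir-121` while
#'   `hsa-mir-1` is untouched).
#' @param keep_arm_suffix treat `-5p`/`-3p` arms as distinct mature
#'   miRNAs (the default); when `FALSE` the arm suffix is stripped.
#' @return An object of class `mirna_policy`.
#' @export
mirna_policy <- function(lowercase = TRUE, merge_locus_suffix = TRUE,
                         keep_arm_suffix = TRUE) {
  structure(
    list(lowercase = isTRUE(lowercase),
         merge_locus_suffix = isTRUE(merge_locus_suffix),
         keep_arm_suffix = isTRUE(keep_arm_suffix)),
    class = "mirna_policy"
  )
}

#' Normalize a miRNA name under a policy
#'
#' Deterministic and idempotent: applying the normalization twice gives
#' the same result as applying it once (suffix stripping runs to a fixed
#' point).
#'
#' @param name character vector of raw miRNA names.
#' @param policy a [mirna_policy()].
#' @return Character vector of normalized names.
#' @export
normalize_mirna_name <- function(name, policy = mirna_policy()) {
  if (length(name) == 0L) return(character(0))
  if (any(is.na(name)) || any(!nzchar(name))) {
    stop("miRNA names must be non-empty strings")
  }
  out <- name
  if (policy$lowercase) out <- tolower(out)
  if (!policy$keep_arm_suffix) out <- sub("-[35]p$", "", out)
  if (policy$merge_locus_suffix) {
    # strip trailing locus copies -1/-2/-3 while the stem still names a
    # numbered miR (e.g. mir-121-1-2 -> mir-121); run to a fixed point
    # so the operation is idempotent by construction
    repeat {
      stripped <- sub("^(.*mi[rR]-?\\d+[a-zA-Z]*)-[123]$", "\\1", out)
      if (identical(stripped, out)) break
      out <- stripped
    }
  }
  out
}

#' Read an association table from a tab-separated edge list
#'
#' The dialect is the plain export format of the curated association
#' databases this package consumes: one edge per line as
#' `left<TAB>right`, extra columns ignored, lines starting with `#`
#' skipped, UTF-8.  Names are normalized (casefolded; miRNA columns
#' additionally folded under `policy`) and exact duplicates removed.
#'
#' @param path path to the TSV file.
#' @param left_layer,right_layer layer labels of the two columns.
#' @param policy a [mirna_policy()] applied to any column whose layer is
#'   `"miRNA"`; its `lowercase` switch also governs casefolding of
#'   non-miRNA names.
#' @param provenance source tag; defaults to the file name.
#' @return An `assoc_table`.
#' @export
parse_association_table <- function(path, left_layer, right_layer,
                                    policy = mirna_policy(),
                                    provenance = basename(path)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    stop("line ", idx[which(bad)[1L]], " of ", path,
         " has fewer than 2 tab-separated fields")
  }
  left <- trimws(vapply(fields, `[[`, "", 1L))
  right <- trimws(vapply(fields, `[[`, "", 2L))
  ok <- nzchar(left) & nzchar(right)
  left <- left[ok]; right <- right[ok]
  if (length(left) == 0L) stop("empty table after filtering: ", path)
  norm <- function(x, layer) {
    if (layer == "miRNA") normalize_mirna_name(x, policy)
    else if (policy$lowercase) tolower(x) else x
  }
  assoc_table(
    data.frame(left = norm(left, left_layer),
               right = norm(right, right_layer),
               stringsAsFactors = FALSE),
    left_layer, right_layer, provenance
  )
}

#' Write an association table as a TSV edge list
#'
#' Writes exactly the dialect [parse_association_table()] reads, so a
#' write/re-parse round trip preserves the edge set.
#'
#' @param table an `assoc_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nzchar(table$provenance)) {
    writeLines(paste0("# ", table$provenance), con)
  }
  writeLines(paste0("# ", table$left_layer, "\t", table$right_layer), con)
  writeLines(paste(table$edges$left, table$edges$right, sep = "\t"), con)
  invisible(path)
}

#' Restrict two tables to their shared miRNA name space
#'
#' The disease--miRNA and miRNA--lncRNA tables generally come from
#' different sources; only miRNAs observed in both can bridge the two
#' layers.  Edges whose miRNA falls outside the intersection are dropped
#' from both tables.  Diseases or lncRNAs that lose all their edges are
#' reported in the `isolated_*` fields; they are not removed from the
#' original tables, so the caller decides whether to keep them in the
#' node registry.
#'
#' @param t1 `assoc_table` with miRNAs on the right (disease--miRNA).
#' @param t2 `assoc_table` with miRNAs on the left (miRNA--lncRNA).
#' @return List with `mirnas` (sorted shared names), `t1`, `t2` (filtered
#'   tables), and `isolated_left` / `isolated_right` (entities of t1's
#'   left and t2's right side that retain zero edges).
#' @export
intersect_mirna_space <- function(t1, t2) {
  if (t1$right_layer != "miRNA" || t2$left_layer != "miRNA") {
    stop("expected miRNAs on the right of t1 and the left of t2")
  }
  shared <- intersect(unique(t1$edges$right), unique(t2$edges$left))
  if (length(shared) == 0L) {
    stop("no shared miRNAs between the two tables; scoring is impossible")
  }
  t1f <- t1; t1f$edges <- t1$edges[t1$edges$right %in% shared, , drop = FALSE]
  t2f <- t2; t2f$edges <- t2$edges[t2$edges$left %in% shared, , drop = FALSE]
  rownames(t1f$edges) <- rownames(t2f$edges) <- NULL
  list(
    mirnas = sort(shared),
    t1 = t1f,
    t2 = t2f,
    isolated_left = setdiff(unique(t1$edges$left), unique(t1f$edges$left)),
    isolated_right = setdiff(unique(t2$edges$right), unique(t2f$edges$right))
  )
}

#' Filter gold-standard pairs to the entities the model can score
#'
#' Gold-standard lncRNA--disease pairs are used only for evaluation;
#' pairs naming a disease or lncRNA absent from the scored universe
#' cannot be ranked and are dropped.
#'
#' @param gold `assoc_table` linking diseases and lncRNAs (either
#'   orientation).
#' @param diseases,lncrnas character vectors of admissible names.
#' @return The filtered `assoc_table` (possibly with zero edges, in
#'   which case a warning is emitted; evaluation refuses empty tables
#'   later).
#' @export
filter_gold_standard <- function(gold, diseases, lncrnas) {
  d_side <- .layer_side(gold, "disease")
  l_side <- .layer_side(gold, "lncRNA")
  if (is.null(d_side) || is.null(l_side)) {
    stop("gold table must link diseases and lncRNAs")
  }
  keep <- gold$edges[[d_side]] %in% diseases & gold$edges[[l_side]] %in% lncrnas
  out <- gold
  out$edges <- unique(gold$edges[keep, , drop = FALSE])
  rownames(out$edges) <- NULL
  if (nrow(out$edges) == 0L) {
    warning("no gold-standard pairs survive filtering")
  }
  out
}

#' Gold pairs as a disease/lncRNA data.frame
#'
#' Canonicalizes the orientation of a gold-standard table.
#'
#' @param gold `assoc_table` linking diseases and lncRNAs.
#' @return data.frame with columns `disease` and `lncrna`.
#' @export
gold_pairs <- function(gold) {
  d_side <- .layer_side(gold, "disease")
  l_side <- .layer_side(gold, "lncRNA")
  if (is.null(d_side) || is.null(l_side)) {
    stop("gold table must link diseases and lncRNAs")
  }
  data.frame(disease = gold$edges[[d_side]], lncrna = gold$edges[[l_side]],
             stringsAsFactors = FALSE)
}
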