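#' Assign tree branches to partitions from clade definitions
#'
#' Clade models require every branch of the phylogeny to belong to exactly
#' one partition (partition 1 is the background). This helper maps each
#' named clade -- given as the set of its tip labels -- to a partition
#' containing every branch inside the clade, optionally including the
#' clade's stem branch. Remaining branches form the background.
#'
#' @param tree An [ape::phylo] tree (rooted or with a basal multifurcation).
#' @param clades A list of clade definitions; each element is either a
#'   character vector of tip labels or a list with elements `tips`,
#'   optional `include_stem` (default `TRUE`) and optional `name`.
#' @param background_label Name for the background partition.
#' @return A `partition_scheme`: integer vector over the rows of
#'   `tree$edge` with values in `1:n_partitions` (1 = background), with
#'   attributes `labels` (partition names) and `tree_hash` dimensions.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' assign_partitions(tr, list(list(tips = c("A", "B"), name = "fg")))
#' @export
assign_partitions <- function(tree, clades,
                              background_label = "background") {
  stopifnot(inherits(tree, "phylo"))
  nedge <- nrow(tree$edge)
  part <- rep(1L, nedge)
  labels <- background_label
  for (k in seq_along(clades)) {
    cl <- clades[[k]]
    if (is.character(cl)) cl <- list(tips = cl)
    tips <- cl$tips
    include_stem <- if (is.null(cl$include_stem)) TRUE else cl$include_stem
    name <- if (is.null(cl$name)) paste0("clade", k) else cl$name
    edges <- clade_edges(tree, tips, include_stem)
    if (any(part[edges] != 1L)) {
      stop("clade '", name, "' overlaps a previously assigned partition")
    }
    part[edges] <- k + 1L
    labels <- c(labels, name)
  }
  new_partition_scheme(part, labels)
}

new_partition_scheme <- function(assignment, labels) {
  assignment <- as.integer(assignment)
  if (!setequal(unique(assignment), seq_len(max(assignment)))) {
    stop("partition indices must be contiguous from 1")
  }
  structure(assignment,
    labels = labels[seq_len(max(assignment))],
    class = "partition_scheme"
  )
}

#' Number of partitions in a scheme
#' @param scheme A `partition_scheme` (or plain integer vector).
#' @return Integer count.
#' @export
n_partitions <- function(scheme) max(as.integer(scheme))

# Edge indices of a clade given its tips; errors if not monophyletic.
clade_edges <- function(tree, tips, include_stem = TRUE) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  tip_ids <- match(tips, tree$tip.label)
  if (length(tip_ids) == 1L) {
    edge <- which(tree$edge[, 2] == tip_ids)
    return(edge) # a single tip: its terminal branch is the whole clade
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- phangorn_descendants(tree, mrca)
  if (!setequal(desc[desc <= ape::Ntip(tree)], tip_ids)) {
    stop(
      "tip set is not monophyletic: clade of their MRCA contains other tips"
    )
  }
  in_clade <- tree$edge[, 1] == mrca | tree$edge[, 1] %in% desc
  edges <- which(in_clade & tree$edge[, 2] %in% desc)
  if (include_stem) {
    stem <- which(tree$edge[, 2] == mrca)
    edges <- c(stem, edges)
  }
  edges
}

# All descendant node ids of an internal node (excluding the node itself).
phangorn_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > ape::Ntip(tree)])
  }
  out
}

#' @export
print.partition_scheme <- function(x, ...) {
  labs <- attr(x, "labels")
  tab <- table(factor(as.integer(x), levels = seq_along(labs), labels = labs))
  cat("Partition scheme (", n_partitions(x), " partitions):\n", sep = "")
  print(tab)
  invisible(x)
}

#' Merge two partitions of a scheme
#'
#' Used to form nested null models: the branches of partition `from` are
#' reassigned to partition `into`, and indices are re-made contiguous.
#'
#' @param scheme A `partition_scheme`.
#' @param from,into Partition indices or labels.
#' @return A new `partition_scheme` with one fewer partition.
#' @export
merge_partitions <- function(scheme, from, into) {
  labs <- attr(scheme, "labels")
  from <- resolve_partition(scheme, from)
  into <- resolve_partition(scheme, into)
  if (from == into) stop("cannot merge a partition with itself")
  x <- as.integer(scheme)
  x[x == from] <- into
  old <- sort(unique(x))
  new_labels <- labs[old]
  new_labels[old == into] <- paste(labs[into], labs[from], sep = "+")
  new_partition_scheme(match(x, old), new_labels)
}

#' Move a single branch to another partition
#'
#' @param scheme A `partition_scheme`.
#' @param edge Edge index (row of `tree$edge`).
#' @param into Partition index or label.
#' @return A new `partition_scheme` (indices re-made contiguous if the
#'   source partition empties).
#' @export
move_branch <- function(scheme, edge, into) {
  into <- resolve_partition(scheme, into)
  x <- as.integer(scheme)
  stopifnot(edge >= 1, edge <= length(x))
  x[edge] <- into
  labs <- attr(scheme, "labels")
  old <- sort(unique(x))
  new_partition_scheme(match(x, old), labs[old])
}

resolve_partition <- function(scheme, p) {
  labs <- attr(scheme, "labels")
  if (is.character(p)) {
    i <- match(p, labs)
    if (is.na(i)) stop("unknown partition label '", p, "'")
    return(i)
  }
  as.integer(p)
}

#' Terminal branch of a tip
#'
#' Convenience lookup of the edge index of the branch leading to a named
#' tip (used e.g. to designate a branch for the misspecification study).
#'
#' @param tree An [ape::phylo] tree.
#' @param tip Tip label.
#' @return Edge index (row of `tree$edge`).
#' @export
tip_branch <- function(tree, tip) {
  id <- match(tip, tree$tip.label)
  if (is.na(id)) stop("unknown tip '", tip, "'")
  which(tree$edge[, 2] == id)
}
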