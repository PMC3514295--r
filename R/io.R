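#' Read an in-frame codon alignment
#'
#' Reads FASTA or PHYLIP (sequential or interleaved, autodetected by
#' [ape::read.dna()]) nucleotide alignments and converts them to codon
#' states. Sequence length must be divisible by 3; codons containing
#' non-ACGT characters become missing; internal stop codons are an error
#' by default.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/content), `"fasta"` or
#'   `"phylip"`.
#' @param stop_codons `"error"` (default) or `"mask"`.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                                 stop_codons = c("error", "mask")) {
  format <- match.arg(format)
  stop_codons <- match.arg(stop_codons)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  dna <- if (format == "fasta") {
    ape::read.dna(path, format = "fasta", as.character = TRUE)
  } else {
    ape::read.dna(path, as.character = TRUE) # ape autodetects phylip dialect
  }
  if (is.list(dna)) stop("sequences have unequal (ragged) lengths")
  m <- toupper(as.matrix(dna))
  seqs <- stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  codon_alignment(seqs, stop_codons = stop_codons)
}

#' Write a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"` (sequential, relaxed names).
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- as_nucleotide_strings(aln)
  names(seqs) <- rownames(aln) %||% paste0("seq", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  } else {
    writeLines(paste(length(seqs), nchar(seqs[1])), con)
    writeLines(sprintf("%-10s  %s", names(seqs), seqs), con)
  }
  invisible(path)
}

#' Read a Newick tree, with optional `#k` branch partition tags
#'
#' Supports the PAML-style dialect in which a `#k` suffix after a tip or
#' internal node attaches that node's stem branch to partition `k`
#' (untagged branches form partition 0/background). Tags on the root are
#' an error (the root has no stem branch). Clade-wide partitions are built
#' with [assign_partitions()] instead.
#'
#' @param path File path, or a Newick string via `text`.
#' @param text Optional literal Newick string.
#' @return A list: `tree` (an [ape::phylo]) and `partition` (a
#'   [partition_scheme()]; single background partition if no tags).
#' @export
read_tree_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- suppressWarnings(tryCatch(ape::read.tree(text = text),
    error = function(e) NULL
  ))
  if (is.null(tree)) stop("malformed Newick string")
  tag_of <- function(labels) {
    m <- regmatches(labels, regexpr("#\\d+$", labels))
    tags <- rep(NA_integer_, length(labels))
    has <- grepl("#\\d+$", labels)
    tags[has] <- as.integer(sub("#", "", m))
    list(tags = tags, clean = sub("#\\d+$", "", labels))
  }
  ntip <- ape::Ntip(tree)
  tip <- tag_of(tree$tip.label)
  tree$tip.label <- tip$clean
  node_tags <- rep(NA_integer_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    nd <- tag_of(tree$node.label)
    node_tags <- nd$tags
    tree$node.label <- nd$clean
    if (all(tree$node.label == "")) tree$node.label <- NULL
  }
  all_tags <- c(tip$tags, node_tags) # indexed by node id
  if (!is.na(all_tags[ntip + 1L])) {
    stop("partition tag on the root is not allowed")
  }
  part <- rep(1L, nrow(tree$edge))
  child_tag <- all_tags[tree$edge[, 2]]
  tagged <- !is.na(child_tag)
  if (any(tagged)) {
    ks <- sort(unique(child_tag[tagged]))
    part[tagged] <- match(child_tag[tagged], ks) + 1L
    labels <- c("background", paste0("#", ks))
  } else {
    labels <- "background"
  }
  list(tree = tree, partition = new_partition_scheme(part, labels))
}

#' Write a Newick tree with `#k` branch partition tags
#'
#' Round-trips with [read_tree_newick()]: partition `p > 1` is written as
#' tag `#(p-1)` on the stem of each branch's child node.
#'
#' @param tree An [ape::phylo].
#' @param partition Optional [partition_scheme()].
#' @param path Optional output path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
write_tree_newick <- function(tree, partition = NULL, path = NULL) {
  if (!is.null(partition)) {
    part <- as.integer(partition)
    ntip <- ape::Ntip(tree)
    if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
    for (e in which(part > 1L)) {
      child <- tree$edge[e, 2]
      tag <- paste0("#", part[e] - 1L)
      if (child <= ntip) {
        tree$tip.label[child] <- paste0(tree$tip.label[child], tag)
      } else {
        tree$node.label[child - ntip] <- paste0(
          tree$node.label[child - ntip], tag
        )
      }
    }
  }
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a simulated dataset to disk
#'
#' Writes the alignment (FASTA and PHYLIP) plus a sidecar JSON with the
#' true site-class labels, the seed and the generating parameter values.
#'
#' @param sim A `sim_dataset` from [simulate_alignment()].
#' @param stem Output path stem (files `<stem>.fasta`, `<stem>.phy`,
#'   `<stem>.json`).
#' @return The sidecar path, invisibly.
#' @export
write_sim_dataset <- function(sim, stem) {
  write_codon_alignment(sim$alignment, paste0(stem, ".fasta"), "fasta")
  write_codon_alignment(sim$alignment, paste0(stem, ".phy"), "phylip")
  side <- list(
    seed = sim$seed,
    true_class = sim$true_class,
    proportions = sim$config$proportions,
    omega = sim$config$omega,
    kappa = sim$config$kappa,
    n_codons = sim$config$n_codons,
    tree = write_tree_newick(sim$config$tree, sim$config$partition)
  )
  jsonlite::write_json(side, paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(stem, ".json"))
}
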