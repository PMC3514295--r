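#' The universal genetic code over the 61 sense codons
#'
#' Builds the lookup tables used by every codon model in the package: the
#' ordered list of sense codons (the universal code; stops TAA, TAG and TGA
#' are excluded), the codon-to-amino-acid map, and the classification of
#' every ordered codon pair as a multi-step change or as a synonymous /
#' nonsynonymous transition / transversion.
#'
#' Codon order is alphabetical (AAA, AAC, AAG, ...), which fixes the state
#' indexing used by rate matrices, alignments and the simulator.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   * `codons`: character vector of the 61 sense codons, in state order;
#'   * `amino_acid`: named character vector, one-letter amino acid per codon;
#'   * `pair_class`: 61 x 61 integer matrix with codes 0 = same codon,
#'     1 = multi-step, 2 = synonymous transition, 3 = synonymous
#'     transversion, 4 = nonsynonymous transition, 5 = nonsynonymous
#'     transversion;
#'   * `pair_class_labels`: labels for the codes above.
#' @examples
#' gc <- genetic_code()
#' gc$pair_class["TTT", "TTC"]  # synonymous transition (both Phe)
#' @export
genetic_code <- function() {
  cached <- .clademodels_env$genetic_code
  if (!is.null(cached)) {
    return(cached)
  }
  nt <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(
    outer(nt, nt, paste0), nt,
    function(ab, c) paste0(ab, c)
  ))
  aa_map <- Biostrings::GENETIC_CODE
  all64 <- sort(all64)
  aa <- aa_map[all64]
  sense <- all64[aa != "*"]
  aa <- aa[aa != "*"]
  stopifnot(length(sense) == 61L)

  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  cod_nt <- do.call(rbind, strsplit(sense, ""))

  pair_class <- matrix(0L, 61, 61, dimnames = list(sense, sense))
  for (i in seq_len(61)) {
    diff <- cod_nt != rep(cod_nt[i, ], each = 61)
    ndiff <- rowSums(diff)
    pair_class[i, ndiff >= 2L] <- 1L
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diff[j, ])
      a <- cod_nt[i, pos]
      b <- cod_nt[j, pos]
      is_ts <- purine[[a]] == purine[[b]]
      is_syn <- aa[[i]] == aa[[j]]
      pair_class[i, j] <- if (is_syn) {
        if (is_ts) 2L else 3L
      } else {
        if (is_ts) 4L else 5L
      }
    }
  }

  out <- structure(
    list(
      codons = sense,
      amino_acid = stats::setNames(aa, sense),
      pair_class = pair_class,
      pair_class_labels = c(
        "0" = "identical", "1" = "multi-step",
        "2" = "synonymous-transition", "3" = "synonymous-transversion",
        "4" = "nonsynonymous-transition", "5" = "nonsynonymous-transversion"
      )
    ),
    class = "genetic_code"
  )
  .clademodels_env$genetic_code <- out
  out
}

.clademodels_env <- new.env(parent = emptyenv())

#' @export
print.genetic_code <- function(x, ...) {
  cat("Universal genetic code:", length(x$codons), "sense codons\n")
  tab <- table(factor(x$pair_class[upper.tri(x$pair_class)],
    levels = 0:5, labels = x$pair_class_labels
  ))
  print(tab[tab > 0])
  invisible(x)
}
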