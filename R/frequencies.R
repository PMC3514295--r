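#' Codon equilibrium frequencies
#'
#' Constructors for the equilibrium distribution over the 61 sense codons
#' used by the codon rate matrix: equal frequencies (1/61, as in the
#' simulation study), the F3x4 approximation built from position-specific
#' nucleotide frequencies of an alignment, or custom values.
#'
#' @param pi Numeric vector of 61 non-negative values summing to 1, named
#'   by codon (any order; reordered internally) or unnamed in state order.
#' @param source Character tag recording how the frequencies were obtained.
#' @param position_freqs Optional 3 x 4 matrix of nucleotide frequencies by
#'   codon position (columns T, C, A, G) when `source = "F3x4"`.
#' @return An object of class `codon_frequencies`: numeric vector of 61
#'   probabilities named by codon, with attributes `source` and (for F3x4)
#'   `position_freqs`.
#' @export
codon_frequencies <- function(pi, source = "custom", position_freqs = NULL) {
  gc <- genetic_code()
  if (!is.null(names(pi))) {
    stopifnot(setequal(names(pi), gc$codons))
    pi <- pi[gc$codons]
  } else {
    stopifnot(length(pi) == 61L)
    names(pi) <- gc$codons
  }
  if (any(pi < 0)) {
    stop("codon frequencies must be non-negative")
  }
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("codon frequencies must sum to 1 (within 1e-12)")
  }
  structure(pi,
    source = source, position_freqs = position_freqs,
    class = "codon_frequencies"
  )
}

#' @rdname codon_frequencies
#' @export
equal_frequencies <- function() {
  codon_frequencies(rep(1 / 61, 61), source = "equal")
}

#' F3x4 codon frequencies from an alignment
#'
#' Empirical nucleotide frequencies are tallied at each of the three codon
#' positions, pooled over all sequences; the frequency of codon ijk is
#' proportional to f1(i) f2(j) f3(k), renormalized over the 61 sense codons
#' (stop-codon mass is redistributed by the normalization). Characters
#' outside ACGT (gaps, ambiguity codes) are skipped, not imputed.
#'
#' @param alignment A codon alignment as returned by [codon_alignment()],
#'   or a character matrix of aligned nucleotide sequences (rows = taxa),
#'   or a character vector of sequences with length divisible by 3.
#' @return A [codon_frequencies()] object with `source = "F3x4"`.
#' @export
f3x4_frequencies <- function(alignment) {
  seqs <- as_nucleotide_strings(alignment)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("empty alignment")
  }
  if (any(nchar(seqs) %% 3 != 0)) {
    stop("alignment length must be divisible by 3")
  }
  nt <- c("T", "C", "A", "G")
  counts <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), nt))
  for (s in seqs) {
    ch <- toupper(strsplit(s, "")[[1]])
    pos <- rep_len(1:3, length(ch))
    keep <- ch %in% nt
    if (any(keep)) {
      counts <- counts + table(
        factor(pos[keep], levels = 1:3),
        factor(ch[keep], levels = nt)
      )
    }
  }
  if (any(rowSums(counts) == 0)) {
    stop("no ACGT characters at one or more codon positions")
  }
  f <- counts / rowSums(counts)
  gc <- genetic_code()
  cod_nt <- do.call(rbind, strsplit(gc$codons, ""))
  pi <- f[1, cod_nt[, 1]] * f[2, cod_nt[, 2]] * f[3, cod_nt[, 3]]
  pi <- pi / sum(pi)
  codon_frequencies(stats::setNames(pi, gc$codons),
    source = "F3x4", position_freqs = f
  )
}

# Coerce the accepted alignment representations to nucleotide strings.
as_nucleotide_strings <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) {
    gc <- genetic_code()
    return(apply(alignment, 1, function(row) {
      paste(ifelse(is.na(row), "---", gc$codons[row]), collapse = "")
    }))
  }
  if (is.matrix(alignment)) {
    return(apply(alignment, 1, paste, collapse = ""))
  }
  as.character(alignment)
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat(
    "Codon frequencies (", attr(x, "source"), "); range [",
    format(min(x), digits = 4), ", ", format(max(x), digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}
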