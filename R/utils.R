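# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Reverse complement of a DNA string
#'
#' @param x A character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence at a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2.
#'
#' @param length Sequence length in bp.
#' @param gc GC content as a fraction in [0, 1].
#' @return A single DNA string.
#' @export
random_dna <- function(length, gc = 0.5) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

# substring() that validates bounds against the sequence.
subseq_checked <- function(seq, start, end) {
  n <- nchar(seq)
  if (start < 1 || end > n || start > end) {
    stop(sprintf("subsequence [%d, %d] outside sequence of length %d",
                 start, end, n))
  }
  substring(seq, start, end)
}

is_dna <- function(x) {
  all(grepl("^[ACGTN]*$", x))
}
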