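# Internal helpers shared across modules.

#' Canonicalize a nucleotide sequence to the internal DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet (U rendered as T);
#' RNA-facing outputs (duplexes, structures) convert back with [to_rna()].
#'
#' @param x character vector of nucleotide sequences (ACGTUN, case
#'   insensitive).
#' @param allow_n keep sequences containing N (default TRUE); validation of
#'   other letters always errors.
#' @return uppercase DNA-alphabet character vector.
#' @export
canonicalize_seq <- function(x, allow_n = TRUE) {
  x <- chartr("acgtun", "ACGTTN", toupper(x))
  x <- chartr("U", "T", x)
  ok <- if (allow_n) grepl("^[ACGTN]*$", x) else grepl("^[ACGT]*$", x)
  if (!all(ok)) {
    bad <- x[!ok][1]
    stop("invalid nucleotide sequence: '", substr(bad, 1, 40), "'", call. = FALSE)
  }
  x
}

#' Render a DNA-alphabet sequence as RNA
#' @param x character vector in the internal DNA alphabet.
#' @return character vector with T replaced by U.
#' @export
to_rna <- function(x) chartr("T", "U", x)

#' Reverse complement
#' @param x character vector of DNA-alphabet sequences.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the chance expectation.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Roman numeral cluster labels I..XX.
roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))

# Deterministic per-purpose seed derived from a master seed; kept < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483591L
}

# Random DNA sequences of given lengths.
random_dna <- function(n, len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (length(len) == 1) len <- rep(len, n)
  vapply(len, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}
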