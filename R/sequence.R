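#' Gene sequence objects
#'
#' A `gene_seq` is a light wrapper around a nucleotide string over the
#' alphabet A/C/G/T together with a short identifier. It stands in for the
#' coding sequence of a gene of interest (in the worked examples, a
#' synthetic 720-nt stand-in for the BCL2 coding sequence).
#'
#' @param nucleotides Character scalar over \{A, C, G, T\}. Lowercase input
#'   is uppercased.
#' @param id Short text label for the sequence.
#'
#' @return An object of class `gene_seq` with fields `id` and `nucleotides`.
#' @examples
#' gene_sequence("ATGGCATAA", id = "toy")
#' @export
gene_sequence <- function(nucleotides, id = "gene") {
  if (!is.character(nucleotides) || length(nucleotides) != 1L ||
      is.na(nucleotides) || !nzchar(nucleotides)) {
    abort_bad_arg("`nucleotides` must be a single non-empty string.")
  }
  nt <- toupper(nucleotides)
  bad <- regexpr("[^ACGT]", nt)
  if (bad > 0L) {
    abort_bad_arg(sprintf(
      "invalid nucleotide '%s' at position %d (alphabet is A, C, G, T)",
      substr(nt, bad, bad), bad
    ))
  }
  structure(list(id = as.character(id), nucleotides = nt),
            class = "gene_seq")
}

#' @export
print.gene_seq <- function(x, ...) {
  n <- nchar(x$nucleotides)
  shown <- if (n > 60) paste0(substr(x$nucleotides, 1, 57), "...")
           else x$nucleotides
  cat(sprintf("<gene_seq> %s (%d nt)\n%s\n", x$id, n, shown))
  invisible(x)
}

#' @export
as.character.gene_seq <- function(x, ...) x$nucleotides

# Accept a gene_seq or a bare string wherever a sequence is expected.
as_nt_string <- function(x) {
  if (inherits(x, "gene_seq")) x$nucleotides
  else if (is.character(x) && length(x) == 1L) x
  else abort_bad_arg("expected a `gene_seq` or a single character string")
}

#' Read the first record of a FASTA file as a gene sequence
#'
#' Reads a (possibly multi-record) FASTA file and returns its first record,
#' uppercased and validated against the A/C/G/T alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A [gene_sequence()] object.
#' @examples
#' fa <- system.file("extdata", "synthetic_bcl2_cds.fasta",
#'                   package = "genomechaos")
#' read_gene_fasta(fa)
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort_bad_arg("FASTA file contains no records")
  nt <- as.character(set[[1L]])
  if (!nzchar(nt)) abort_bad_arg("first FASTA record is empty")
  id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  gene_sequence(nt, id = id)
}

#' Write a gene sequence to FASTA
#'
#' @param seq A [gene_sequence()] object.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(seq, path, width = 60) {
  nt <- as_nt_string(seq)
  id <- if (inherits(seq, "gene_seq")) seq$id else "gene"
  set <- Biostrings::DNAStringSet(setNames(nt, id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Randomly mutate a gene sequence
#'
#' Applies one cell division's worth of substitution mutations: every
#' position is independently substituted with probability `rate`, and a
#' substituted base is drawn uniformly from the three alternative bases.
#' The mutation model is substitution-only, so sequence length is
#' preserved and the number of recorded mutations always equals the
#' Hamming distance between input and output.
#'
#' Randomness comes from R's global RNG; call [set.seed()] beforehand for
#' reproducible draws.
#'
#' @param seq A [gene_sequence()] object (or bare nucleotide string).
#' @param rate Per-nucleotide, per-division substitution probability in
#'   \[0, 1\].
#' @return A list with components `sequence` (the mutated `gene_seq`) and
#'   `mutations`, a tibble with one row per substitution and columns
#'   `position` (1-based), `ref` and `alt`, ordered by position.
#' @examples
#' set.seed(1)
#' mutate_gene(gene_sequence("ATGGCATAA"), rate = 0.5)
#' @export
mutate_gene <- function(seq, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    abort_bad_arg("`rate` must be a single probability in [0, 1].")
  }
  nt <- as_nt_string(seq)
  if (!inherits(seq, "gene_seq")) seq <- gene_sequence(nt)
  chars <- strsplit(nt, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  if (length(hit)) {
    ref <- chars[hit]
    # uniform over the 3 non-reference bases: offset the reference index
    # by 1..3 modulo 4
    ridx <- match(ref, bases)
    alt <- bases[((ridx - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    chars[hit] <- alt
    rec <- tibble(position = hit, ref = ref, alt = alt)
  } else {
    rec <- tibble(position = integer(), ref = character(), alt = character())
  }
  list(
    sequence = gene_sequence(paste(chars, collapse = ""), id = seq$id),
    mutations = rec
  )
}

#' Number of cell divisions until the first mutation
#'
#' Simulates successive cell divisions of a sequence of `length`
#' nucleotides, each division introducing substitutions independently at
#' probability `rate` per nucleotide, and returns the 1-based index of the
#' first division at which at least one substitution occurs. The waiting
#' time is geometric with per-division success probability
#' \eqn{1 - (1 - rate)^{length}}.
#'
#' @param length Sequence length in nucleotides (>= 1).
#' @param rate Per-nucleotide, per-division substitution probability in
#'   (0, 1\].
#' @param max_divisions Hard cap on the number of divisions simulated;
#'   exceeding it raises an error rather than silently truncating.
#' @return Integer division count (>= 1).
#' @examples
#' set.seed(1)
#' divisions_until_first_mutation(720, 1e-5)
#' @export
divisions_until_first_mutation <- function(length, rate,
                                           max_divisions = 1e7) {
  if (!is.numeric(length) || length < 1) abort_bad_arg("`length` must be >= 1")
  if (!is.numeric(rate) || rate <= 0 || rate > 1) {
    abort_bad_arg("`rate` must be in (0, 1]")
  }
  if (!is.numeric(max_divisions) || max_divisions < 1) {
    abort_bad_arg("`max_divisions` must be >= 1")
  }
  length <- as.integer(length)
  done <- 0L
  block <- 1024L
  while (done < max_divisions) {
    n <- as.integer(min(block, max_divisions - done))
    hits <- rbinom(n, size = length, prob = rate)
    first <- which(hits > 0L)
    if (length(first)) return(done + first[1L])
    done <- done + n
  }
  stop(sprintf(
    "no mutation within max_divisions = %g divisions (rate %g, length %d)",
    max_divisions, rate, length
  ), call. = FALSE)
}

#' Monte Carlo mean waiting time to a first mutation
#'
#' Replicates [divisions_until_first_mutation()] `n_iterations` times and
#' summarises the division counts. The theoretical mean is
#' \eqn{1 / (1 - (1 - rate)^{length})}.
#'
#' @inheritParams divisions_until_first_mutation
#' @param n_iterations Number of Monte Carlo replicates (>= 1).
#' @return A one-row tibble with columns `mean_divisions`, `se` (standard
#'   error of the mean) and `n`.
#' @examples
#' set.seed(1)
#' mean_divisions_to_first_mutation(720, 1e-5, n_iterations = 200)
#' @export
mean_divisions_to_first_mutation <- function(length, rate, n_iterations,
                                             max_divisions = 1e7) {
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    abort_bad_arg("`n_iterations` must be >= 1")
  }
  draws <- vapply(
    seq_len(n_iterations),
    function(i) divisions_until_first_mutation(length, rate, max_divisions),
    numeric(1)
  )
  se <- if (n_iterations > 1L) sd(draws) / sqrt(n_iterations) else 0
  tibble(mean_divisions = mean(draws), se = se, n = as.integer(n_iterations))
}

#' Translate a coding sequence to protein
#'
#' Translates frame 0 of a coding sequence under the standard genetic
#' code. A single terminal stop codon is dropped; an internal stop codon
#' is an error that reports the offending codon index (1-based).
#'
#' @param seq A [gene_sequence()] (or bare string) whose length is a
#'   multiple of 3.
#' @return A single character string of one-letter amino-acid codes.
#' @examples
#' translate_gene("ATGGCATAA")  # "MA"
#' @export
translate_gene <- function(seq) {
  nt <- as_nt_string(toupper_seq(seq))
  n <- nchar(nt)
  if (n == 0L || n %% 3L != 0L) {
    abort_bad_arg(sprintf(
      "sequence length %d is not a positive multiple of 3", n
    ))
  }
  codons <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) {
    abort_bad_arg(sprintf("unrecognised codon at codon index %d",
                          which(is.na(aa))[1L]))
  }
  stops <- which(aa == "*")
  n_codons <- length(aa)
  if (length(stops) && any(stops < n_codons)) {
    abort_bad_arg(sprintf("internal stop codon '%s' at codon index %d",
                          codons[stops[1L]], stops[1L]))
  }
  if (length(stops)) aa <- aa[-n_codons]
  if (!length(aa)) abort_bad_arg("translation is empty (lone stop codon)")
  paste(aa, collapse = "")
}

toupper_seq <- function(seq) {
  if (inherits(seq, "gene_seq")) seq else toupper(as_nt_string(seq))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Sequences of equal length: `gene_seq` objects or bare
#'   strings (nucleotide or protein).
#' @return Integer count of differing positions.
#' @examples
#' hamming_distance("AAAA", "TTTT")
#' @export
hamming_distance <- function(a, b) {
  sa <- as_nt_string_any(a)
  sb <- as_nt_string_any(b)
  if (nchar(sa) != nchar(sb)) {
    abort_bad_arg(sprintf("length mismatch: %d vs %d", nchar(sa), nchar(sb)))
  }
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  sum(ca != cb)
}

as_nt_string_any <- function(x) {
  if (inherits(x, "gene_seq")) x$nucleotides
  else if (is.character(x) && length(x) == 1L) x
  else abort_bad_arg("expected a `gene_seq` or a single character string")
}

#' Ungapped percent identity between equal-length sequences
#'
#' @inheritParams hamming_distance
#' @return Percentage of matching positions, rounded to two decimals.
#' @examples
#' percent_identity("MAGW", "MAGV")  # 75
#' @export
percent_identity <- function(a, b) {
  sa <- as_nt_string_any(a)
  sb <- as_nt_string_any(b)
  if (!nzchar(sa) || !nzchar(sb)) abort_bad_arg("sequences must be non-empty")
  n <- nchar(sa)
  if (n != nchar(sb)) {
    abort_bad_arg(sprintf("length mismatch: %d vs %d", n, nchar(sb)))
  }
  round(100 * (n - hamming_distance(sa, sb)) / n, 2)
}
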