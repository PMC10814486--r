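# Shared fixtures and independent oracles.

fixture_fasta <- function() {
  system.file("extdata", "synthetic_bcl2_cds.fasta", package = "genomechaos")
}

fixture_table1 <- function() {
  system.file("extdata", "table1.csv", package = "genomechaos")
}

# substitute a single base (1-based position) in a nucleotide string
substitute_base <- function(nt, pos, base) {
  substr(nt, pos, pos) <- base
  nt
}

# closed-form mean waiting time: geometric with p = 1 - (1 - rate)^length
geometric_mean_divisions <- function(length, rate) {
  1 / (-expm1(length * log1p(-rate)))
}

clones_tbl <- function(fcm) {
  tibble::tibble(
    clone_id = sprintf("c%03d", seq_along(fcm)),
    fcm_percent = fcm
  )
}

# brute-force permutation count by recursive enumeration (oracle for n!)
enumerate_permutations <- function(n) {
  if (n == 0L) return(1L)
  perms <- function(items) {
    if (length(items) <= 1L) return(list(items))
    out <- list()
    for (i in seq_along(items)) {
      for (rest in perms(items[-i])) out[[length(out) + 1L]] <- c(items[i], rest)
    }
    out
  }
  length(perms(seq_len(n)))
}
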