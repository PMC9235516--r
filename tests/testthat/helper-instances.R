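# Abstract k-mer sequences built from integer labels: the sketching and bias
# machinery depend only on k-mer identity, so fixed-width labels are enough
# for layout-controlled fixtures.
abstract_seq <- function(ids) {
  kmer_seq(sprintf("K%05d", ids))
}

# Worked layout with two isolated shared k-mers (I = 2, U = 10, J = 0.2):
# each shared k-mer has unshared window neighbours on both sides.
layout_isolated <- function() {
  list(
    A = kmer_seq(c("AA", "CC", "GG", "TT", "AC", "AG")),
    B = kmer_seq(c("CA", "CC", "GA", "TA", "AC", "CT"))
  )
}

# Same I, U, J but the two shared k-mers are adjacent, so each one's window
# neighbourhood contains the other shared k-mer.
layout_adjacent <- function() {
  list(
    A = kmer_seq(c("AA", "CC", "AC", "GG", "TT", "AG")),
    B = kmer_seq(c("CA", "CC", "AC", "GA", "TA", "CT"))
  )
}

# Minimal instance for the per-shared-k-mer joint minimizer probability:
# one shared k-mer flanked by unshared k-mers (w = 2, five distinct values).
tau_isolated_instance <- function() {
  list(A = kmer_seq(c("AA", "CC", "GG")), B = kmer_seq(c("TT", "CC", "AT")))
}

# Variant where the right flank is also shared (four distinct values).
tau_shared_flank_instance <- function() {
  list(A = kmer_seq(c("AA", "CC", "GG")), B = kmer_seq(c("TT", "CC", "GG")))
}

# Random tiny pair with at most n distinct k-mers (for exact enumeration).
tiny_random_pair <- function(n = 8, L = 6) {
  ids <- seq_len(n)
  list(A = abstract_seq(sample(ids, L)), B = abstract_seq(sample(ids, L)))
}
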