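# Internal sequence helpers. Sequences live as plain uppercase strings over
# {A,C,G,T,N}; per-base work uses an integer encoding (A=1,C=2,G=3,T=4,N=5).

.BASES <- c("A", "C", "G", "T", "N")
.CODE_A <- 1L; .CODE_C <- 2L; .CODE_G <- 3L; .CODE_T <- 4L; .CODE_N <- 5L

.enc_table <- local({
  tab <- rep(NA_integer_, 127L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("N")] <- 5L
  tab
})

seq_encode <- function(s) {
  v <- .enc_table[utf8ToInt(s)]
  if (anyNA(v)) stop("sequence contains symbols outside {A,C,G,T,N}")
  v
}

.dec_table <- vapply(.BASES, utf8ToInt, integer(1))

seq_decode <- function(v) {
  intToUtf8(.dec_table[v])
}

# complement in integer code; N stays N
.comp_table <- c(4L, 3L, 2L, 1L, 5L)

revcomp_int <- function(v) .comp_table[rev(v)]

#' Reverse complement of a nucleotide string
#' @param s uppercase sequence over {A,C,G,T,N}.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(s) seq_decode(revcomp_int(seq_encode(s)))

#' GC fraction of a sequence over its non-N bases
#' @param x sequence string (or internal integer encoding).
#' @return GC fraction in [0, 1]; NA for an all-N sequence.
#' @export
gc_fraction <- function(x) {
  if (is.character(x)) x <- seq_encode(x)
  n_gc <- sum(x == .CODE_C | x == .CODE_G)
  n_acgt <- sum(x != .CODE_N)
  if (n_acgt == 0L) return(NA_real_)
  n_gc / n_acgt
}

# start positions (1-based) of CG dinucleotides; N never matches
cpg_starts <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer(0))
  which(v[-n] == .CODE_C & v[-1L] == .CODE_G)
}

# all positions that are the C or the G of a CG dinucleotide
cpg_context_sites <- function(v) {
  p <- cpg_starts(v)
  unique.default(sort.int(c(p, p + 1L)))
}

# random sequence with a given GC fraction (iid bases)
random_seq_int <- function(n, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
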