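## Shared fixtures, all built in code.

## deterministic random genome string over A/C/G/T
randomBases <- function(n, seed = 1L) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## a small non-uniform order-1 chain used across tests
toyChain1 <- function() {
  tt <- matrix(c(0.70, 0.10, 0.10, 0.10,
                 0.10, 0.60, 0.20, 0.10,
                 0.05, 0.15, 0.60, 0.20,
                 0.25, 0.25, 0.10, 0.40), nrow = 4, byrow = TRUE)
  markovModelFromTable(tt, 1L)
}

## write a FASTA to a temp file, return its path
tempFasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

## brute-force O(L^2) DFT magnitudes, one-sided (independent oracle)
bruteDftMagnitudes <- function(x) {
  L <- length(x)
  f <- 0:floor(L / 2)
  sapply(f, function(k) {
    ang <- -2 * pi * k * (0:(L - 1)) / L
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))
  })
}
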