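# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code with the package implementations.

apen_bruteforce <- function(x, m, r) {
  phi <- function(mm) {
    N <- length(x)
    n <- N - mm + 1L
    logs <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r) {
          cnt <- cnt + 1L
        }
      }
      logs[i] <- log(cnt / n)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1L)
}

sampen_bruteforce <- function(x, m, r) {
  count_matches <- function(mm) {
    N <- length(x)
    n <- N - m            # same template count at both lengths
    cnt <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  -log(A / B)
}

# closed-form expectation check helper
expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
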