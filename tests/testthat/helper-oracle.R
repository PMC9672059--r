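# Independent pure-R oracle for the optimal-string-alignment (restricted
# Damerau-Levenshtein) distance: full dynamic-programming matrix, written
# without reference to the package's compiled kernel.
osa_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# brute-force fuzzy scan: every backbone name is examined directly (no
# index, no candidate blocking). The stage's documented contract applies:
# distance threshold by query length, genus token within genus_max_distance
# sharing the initial letter, minimum distance wins.
brute_force_best <- function(canonical, backbone_names,
                             config = match_config()) {
  threshold <- if (nchar(canonical) <= 8) config$max_edit_distance_short
  else config$max_edit_distance_long
  q <- tolower(canonical)
  qg <- strsplit(q, " ")[[1]][1]
  ok <- vapply(tolower(backbone_names), function(x) {
    xg <- strsplit(x, " ")[[1]][1]
    substr(xg, 1, 1) == substr(qg, 1, 1) &&
      osa_oracle(qg, xg) <= config$genus_max_distance
  }, logical(1))
  d <- rep(NA_integer_, length(backbone_names))
  d[ok] <- vapply(tolower(backbone_names[ok]),
                  function(x) osa_oracle(q, x), integer(1))
  within <- which(!is.na(d) & d <= threshold)
  if (length(within) == 0) return(integer(0))
  within[d[within] == min(d[within])]
}
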