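# Compact letter display by insertion-absorption.
#
# Groups sharing at least one letter do not differ significantly; groups
# sharing no letter do. Input is a symmetric matrix of (adjusted) pairwise
# p-values with group names on the dimnames.

letters_from_pmatrix <- function(pmat, alpha = 0.05, alphabet = letters) {
  groups <- rownames(pmat)
  k <- length(groups)
  stopifnot(k >= 1, identical(rownames(pmat), colnames(pmat)))
  sets <- list(seq_len(k)) # start: everyone shares one letter
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      p <- pmat[i, j]
      if (is.finite(p) && p < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (i %in% s && j %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (u in seq_along(new_sets)) {
          for (v in seq_along(new_sets)) {
            if (u != v && keep[u] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
              keep[u] <- FALSE
            }
          }
        }
        sets <- unique(new_sets[keep])
      }
    }
  }
  # order letters by the first group they contain
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  if (length(sets) > length(alphabet)) {
    alphabet <- c(alphabet, paste0(alphabet, seq_len(length(sets))))
  }
  set_letter <- alphabet[seq_along(sets)]
  out <- vapply(seq_len(k), function(g) {
    paste(set_letter[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

# Greek alphabet for the large-prey letter convention in figures.
greek_letters <- function(n = 24) {
  vapply(seq_len(n), function(i) intToUtf8(0x03B0 + i), character(1))
}
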