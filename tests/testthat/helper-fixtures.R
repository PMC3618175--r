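# Shared fixtures, built once per test run. All inputs are generated in
# code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# A mid-sized catalogue shared by the matching/category/acceptance tests.
shared_catalogue <- function() {
  if (is.null(.fixture_env$catalogue)) {
    .fixture_env$catalogue <- build_catalogue(25, seed = 42)
  }
  .fixture_env$catalogue
}

# Rebuild the full song_type (with glyph parameters) for a catalogue row.
catalogue_type <- function(catalogue, i) {
  structure(list(song_type_id = catalogue$types$song_type_id[i],
                 species = catalogue$types$species[i],
                 elements = catalogue$types$elements[[i]]),
            class = "song_type")
}

# Independent reference LCS: plain memoised recursion, no shared code with
# the package implementation.
lcs_ref <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) rec(i - 1L, j - 1L) + 1L
         else max(rec(i - 1L, j), rec(i, j - 1L))
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Exhaustive Mann-Whitney null: enumerate every placement of the m x-ranks
# among m+n tie-free values and tabulate U (min convention not applied; the
# U of the first sample is returned per arrangement).
mw_brute_distribution <- function(m, n) {
  combos <- utils::combn(m + n, m)
  u <- apply(combos, 2, function(idx) sum(idx) - m * (m + 1) / 2)
  tab <- table(factor(u, levels = 0:(m * n)))
  as.numeric(tab) / ncol(combos)
}
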