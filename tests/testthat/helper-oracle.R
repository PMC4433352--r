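# Independent oracles, deliberately naive: they re-derive expected values
# from first principles rather than reusing the package's fast paths.

# All consistent qualitative states of a model by brute force: every one of
# the (2*3)^|V| candidate assignments is checked against the QDE constraints
# directly (magnitude in {zer, pos}, derivative in {neg, zer, pos}).
brute_force_states <- function(model) {
  qde <- derive_qde(model)
  vars <- qde$variables
  nv <- length(vars)
  mags <- expand.grid(rep(list(c("zer", "pos")), nv),
                      stringsAsFactors = FALSE)
  ders <- expand.grid(rep(list(c("neg", "zer", "pos")), nv),
                      stringsAsFactors = FALSE)
  keep_mag <- list(); keep_der <- list()
  for (i in seq_len(nrow(mags))) {
    mg <- as.character(mags[i, ])
    fs <- vapply(qde$transitions, function(tr) {
      flux_sign(mg[tr$inputs])
    }, character(1L))
    allowed <- lapply(qde$constraints, function(cn) {
      sum_signs(ifelse(cn$coef > 0L, "+", "-"), fs[cn$transition])
    })
    for (j in seq_len(nrow(ders))) {
      dr <- as.character(ders[j, ])
      ok <- all(vapply(seq_len(nv), function(v) dr[v] %in% allowed[[v]],
                       logical(1L)))
      if (ok) {
        keep_mag[[length(keep_mag) + 1L]] <- mg
        keep_der[[length(keep_der) + 1L]] <- dr
      }
    }
  }
  df <- as.data.frame(
    lapply(seq_len(nv), function(v) {
      paste(vapply(keep_mag, `[`, character(1L), v),
            vapply(keep_der, `[`, character(1L), v), sep = ",")
    }), col.names = vars, check.names = FALSE)
  colnames(df) <- vars
  states_from_table(df)
}

# Canonical sorted key strings of a state set, for set comparisons.
state_keys <- function(states) {
  df <- as.data.frame(states)
  sort(apply(df, 1L, paste, collapse = ";"))
}

expect_same_states <- function(a, b) {
  expect_identical(state_keys(a), state_keys(b))
}

# A tiny deterministic library for property tests.
toy_library <- function() generate_library(c("A", "B"), c("E", "F"))
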