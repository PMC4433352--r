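# Sign-algebra qualitative engine.
#
# Variables (reactant concentrations) take qualitative values
# <magnitude, derivative>. Magnitudes range over {zer, pos} (concentrations
# are nonnegative), derivatives over {neg, zer, pos}. A model's qualitative
# semantics is a QDE: one constraint per variable expressing its derivative
# as the signed sum of the mass-action flux signs of the transitions that
# produce (+) or consume (-) it.

SIGN_LEVELS <- c("neg", "zer", "pos")
# derivative codes: 1 = neg, 2 = zer, 3 = pos
# derivative-set codes: 1 = {zer}, 2 = {pos}, 3 = {neg}, 4 = {neg, zer, pos}
DSET_SIZE <- c(1L, 1L, 1L, 3L)
DSET_FIXED_DERIV <- c(2L, 3L, 1L, NA_integer_)

check_signs <- function(x) {
  x <- as.character(x)
  if (!all(x %in% SIGN_LEVELS)) {
    stop("signs must be one of 'neg', 'zer', 'pos'")
  }
  x
}

#' Qualitative flux sign of a mass-action reaction
#'
#' Under single-step mass-action kinetics a reaction's rate is a monomial in
#' its input concentrations, so its sign is the product of the input
#' magnitude signs: zero as soon as any input is zero, otherwise positive
#' (for nonnegative concentrations).
#'
#' @param magnitudes non-empty character vector of input magnitude signs
#'   (`"zer"`/`"pos"`; `"neg"` is accepted and handled by sign product).
#' @return a single sign.
#' @export
flux_sign <- function(magnitudes) {
  magnitudes <- check_signs(magnitudes)
  if (length(magnitudes) == 0L) stop("a reaction has at least one input")
  if (any(magnitudes == "zer")) return("zer")
  if (sum(magnitudes == "neg") %% 2L == 1L) return("neg")
  "pos"
}

#' Achievable signs of a signed sum
#'
#' Given terms that each carry a coefficient sign (`+` or `-`) and a value
#' sign, returns the set of signs the sum can take: all-zero terms force
#' zero, same-direction terms force that direction, and opposing nonzero
#' terms are qualitatively unresolvable (any sign).
#'
#' @param coefs character (`"+"`/`"-"`) or numeric (+1/-1) coefficient signs.
#' @param signs character vector of term value signs.
#' @return character vector, a subset of `c("neg", "zer", "pos")`.
#' @examples
#' sum_signs("+", "pos")                # "pos"
#' sum_signs(c("+", "-"), c("pos", "pos"))  # all three
#' @export
sum_signs <- function(coefs, signs) {
  if (length(coefs) != length(signs)) stop("coefs and signs lengths differ")
  if (length(coefs) == 0L) return("zer")
  signs <- check_signs(signs)
  if (is.character(coefs)) {
    if (!all(coefs %in% c("+", "-"))) stop("coefs must be '+' or '-'")
    coefs <- ifelse(coefs == "+", 1L, -1L)
  }
  val <- ifelse(signs == "zer", 0L, ifelse(signs == "pos", 1L, -1L)) * coefs
  haspos <- any(val > 0L); hasneg <- any(val < 0L)
  if (haspos && hasneg) return(SIGN_LEVELS)
  if (haspos) return("pos")
  if (hasneg) return("neg")
  "zer"
}

#' Derive the qualitative differential equation of a model
#'
#' Builds the QDE representation of a Petri-net model: variables are the
#' places, every variable takes the signs quantity space, and each variable
#' gets one constraint stating that its derivative lies in the signed sum of
#' the flux signs of its transitions (`+` per producing transition, `-` per
#' consuming one; a variable both consumed and produced by one transition
#' contributes both terms). The QDE transition set (domain-boundary rules)
#' is not used by the state-set semantics and is left empty.
#'
#' @param model a `qml_model`.
#' @return an object of class `qml_qde` with elements `variables`,
#'   `quantity_space`, `constraints` (one per variable: `coef` and
#'   `transition` integer vectors) and `transitions` (input/output place
#'   indices plus signatures).
#' @export
derive_qde <- function(model) {
  stopifnot(inherits(model, "qml_model"))
  vars <- model$places
  trans <- lapply(model$components, function(cc) {
    list(inputs = match(unique(cc$inputs), vars),
         outputs = match(unique(cc$outputs), vars),
         signature = component_signature(cc))
  })
  constraints <- lapply(seq_along(vars), function(vi) {
    coef <- integer(0L); tr <- integer(0L)
    for (ti in seq_along(trans)) {
      if (vi %in% trans[[ti]]$inputs) { coef <- c(coef, -1L); tr <- c(tr, ti) }
      if (vi %in% trans[[ti]]$outputs) { coef <- c(coef, 1L); tr <- c(tr, ti) }
    }
    list(variable = vars[[vi]], coef = coef, transition = tr)
  })
  if (any(vapply(constraints, function(cn) length(cn$coef), integer(1L)) == 0L)) {
    stop("every variable must appear in at least one constraint")
  }
  structure(list(variables = vars,
                 quantity_space = stats::setNames(
                   rep("signs", length(vars)), vars),
                 constraints = constraints,
                 transitions = trans),
            class = "qml_qde")
}

#' @export
print.qml_qde <- function(x, ...) {
  cat("<QDE> ", length(x$variables), " variables, ",
      length(x$transitions), " flux terms\n", sep = "")
  for (cn in x$constraints) {
    lhs <- paste0("d(", cn$variable, ")")
    rhs <- paste(ifelse(cn$coef > 0L, "+", "-"),
                 paste0("v", cn$transition), collapse = " ")
    cat("  ", lhs, " = ", rhs, "\n", sep = "")
  }
  invisible(x)
}

# ---- state sets -----------------------------------------------------------

# A qml_states object is either
#   factored:     one row per magnitude assignment (rows disjoint, exact):
#                 mag  logical matrix  (TRUE = pos)
#                 dset integer matrix  (derivative-set codes)
#   materialized: explicit states:
#                 mag logical, deriv integer (1 neg / 2 zer / 3 pos), key
new_states_factored <- function(vars, mag, dset) {
  structure(list(vars = vars, form = "factored", mag = mag, dset = dset),
            class = "qml_states")
}

new_states_materialized <- function(vars, mag, deriv) {
  key <- encode_state_keys(mag, deriv)
  o <- order(key)
  structure(list(vars = vars, form = "materialized",
                 mag = mag[o, , drop = FALSE],
                 deriv = deriv[o, , drop = FALSE],
                 key = key[o]),
            class = "qml_states")
}

# numeric key = sum over vars of (mag*3 + deriv-1) * 6^(i-1); exact for
# up to 20 variables (6^20 < 2^53).
encode_state_keys <- function(mag, deriv) {
  n <- ncol(mag)
  if (n > 20L) stop("state keys support at most 20 variables")
  w <- 6 ^ (seq_len(n) - 1L)
  as.vector((mag * 3 + deriv - 1) %*% w)
}

decode_state_keys <- function(key, nvar) {
  mag <- matrix(FALSE, length(key), nvar)
  deriv <- matrix(0L, length(key), nvar)
  for (i in seq_len(nvar)) {
    v <- floor(key / 6 ^ (i - 1L)) %% 6
    mag[, i] <- v >= 3
    deriv[, i] <- as.integer(v %% 3 + 1)
  }
  list(mag = mag, deriv = deriv)
}

#' Number of states in a state set
#'
#' Exact, without materializing the set.
#'
#' @param states a `qml_states` object.
#' @return a number (may exceed integer range for large models).
#' @export
state_count <- function(states) {
  stopifnot(inherits(states, "qml_states"))
  if (states$form == "materialized") return(length(states$key))
  sum(3 ^ rowSums(states$dset == 4L))
}

#' Enumerate the consistent qualitative states of a model
#'
#' The set of all complete assignments of `<magnitude, derivative>` pairs to
#' the model's variables such that every variable's derivative sign is
#' achievable under its QDE constraint given the magnitudes. Magnitudes
#' range over `{zer, pos}`; flux signs depend only on magnitudes, so for a
#' fixed magnitude assignment the per-variable derivative sets are
#' independent and the set is stored factored (one block per magnitude
#' assignment) rather than materialized.
#'
#' @param x a `qml_model` or `qml_qde`.
#' @param cap refuse models with more than this many variables (default 20;
#'   the factored representation enumerates `2^|V|` magnitude blocks).
#' @return a `qml_states` object (factored).
#' @export
enumerate_states <- function(x, cap = getOption("qmlearn.var_cap", 20L)) {
  qde <- if (inherits(x, "qml_model")) derive_qde(x) else x
  stopifnot(inherits(qde, "qml_qde"))
  nv <- length(qde$variables)
  if (nv > cap) {
    stop("model has ", nv, " variables, above the enumeration cap of ", cap)
  }
  blocks <- enum_blocks(qde, seq_len(nv), seq_len(nv))
  new_states_factored(qde$variables, blocks$mag, blocks$dset)
}

# Walk all 2^|enum_idx| magnitude assignments in chunks, computing for each
# the derivative-set codes of the variables in `code_idx` (whose constraint
# transitions must draw all their inputs from enum_idx), and fold the chunks
# through `collect(mag, dset)` so large enumerations never materialize at
# once.
enum_fold <- function(qde, enum_idx, code_idx, collect, chunk_bits = 16L) {
  ne <- length(enum_idx)
  ntot <- 2 ^ ne
  pos_in_enum <- match(seq_along(qde$variables), enum_idx)
  needed_t <- sort(unique(unlist(lapply(code_idx, function(vi) {
    qde$constraints[[vi]]$transition
  }))))
  t_inputs <- lapply(qde$transitions[needed_t], function(tr) {
    ii <- pos_in_enum[tr$inputs]
    if (anyNA(ii)) stop("internal: transition input outside enumerated set")
    ii
  })
  done <- 0
  chunk <- 2 ^ min(chunk_bits, ne)
  while (done < ntot) {
    n <- min(chunk, ntot - done)
    mag <- matrix(FALSE, n, ne)
    for (i in seq_len(ne)) {
      period <- 2 ^ (i - 1L)
      if (period < chunk) {
        # chunks start at multiples of the chunk size, so low-bit patterns
        # align with the chunk boundary
        mag[, i] <- rep_len(rep(c(FALSE, TRUE), each = period), n)
      } else {
        mag[, i] <- floor(done / period) %% 2 == 1
      }
    }
    on <- matrix(TRUE, n, length(needed_t))
    for (j in seq_along(needed_t)) {
      for (ii in t_inputs[[j]]) on[, j] <- on[, j] & mag[, ii]
    }
    dset <- matrix(0L, n, length(code_idx))
    for (k in seq_along(code_idx)) {
      cn <- qde$constraints[[code_idx[[k]]]]
      tj <- match(cn$transition, needed_t)
      haspos <- rep(FALSE, n); hasneg <- rep(FALSE, n)
      for (m in seq_along(tj)) {
        if (cn$coef[[m]] > 0L) haspos <- haspos | on[, tj[[m]]]
        else hasneg <- hasneg | on[, tj[[m]]]
      }
      dset[, k] <- 1L + haspos * 1L + hasneg * 2L  # 1 Z, 2 P, 3 N, 4 all
    }
    collect(mag, dset)
    done <- done + n
  }
  invisible(NULL)
}

# Materialized variant: one row per magnitude assignment.
enum_blocks <- function(qde, enum_idx, code_idx, chunk_bits = 16L) {
  mag_out <- list(); dset_out <- list()
  enum_fold(qde, enum_idx, code_idx, function(mag, dset) {
    mag_out[[length(mag_out) + 1L]] <<- mag
    dset_out[[length(dset_out) + 1L]] <<- dset
  }, chunk_bits = chunk_bits)
  list(mag = do.call(rbind, mag_out), dset = do.call(rbind, dset_out))
}

# Expand a set of factored blocks into unique materialized state keys.
materialize_keys <- function(mag, dset) {
  n <- ncol(mag)
  w <- 6 ^ (seq_len(n) - 1L)
  fixed <- matrix(DSET_FIXED_DERIV[dset], nrow(dset), n)
  base <- rowSums(mag * 3 * rep(w, each = nrow(mag)), na.rm = TRUE) +
    rowSums((fixed - 1) * rep(w, each = nrow(mag)), na.rm = TRUE)
  keys <- vector("list", nrow(mag))
  for (r in seq_len(nrow(mag))) {
    k <- base[[r]]
    free <- which(dset[r, ] == 4L)
    for (v in free) k <- as.vector(outer(k, (0:2) * w[[v]], "+"))
    keys[[r]] <- k
  }
  unique(unlist(keys))
}

#' Materialize a state set
#'
#' Converts a factored state set into the explicit list-of-states form.
#' Guarded by a size limit since factored sets can be astronomically large.
#'
#' @param states a `qml_states` object.
#' @param limit refuse to materialize more than this many states.
#' @return a materialized `qml_states`.
#' @export
materialize_states <- function(states, limit = 2e6) {
  stopifnot(inherits(states, "qml_states"))
  if (states$form == "materialized") return(states)
  if (state_count(states) > limit) {
    stop("state set too large to materialize (", state_count(states),
         " states)")
  }
  keys <- materialize_keys(states$mag, states$dset)
  d <- decode_state_keys(keys, length(states$vars))
  new_states_materialized(states$vars, d$mag, d$deriv)
}

#' Project a state set onto a subset of variables
#'
#' Restricts every state to the requested variables and removes duplicate
#' restricted assignments. Projection never increases the state count.
#'
#' @param states a `qml_states` object.
#' @param variables character vector, a subset of `states$vars`.
#' @return a materialized `qml_states` over `variables`.
#' @export
project_states <- function(states, variables) {
  stopifnot(inherits(states, "qml_states"))
  miss <- setdiff(variables, states$vars)
  if (length(miss) > 0L) {
    stop(structure(
      class = c("qml_missing_variable", "error", "condition"),
      list(message = paste0("variable(s) absent from the state set: ",
                            paste(miss, collapse = ", ")),
           call = sys.call())))
  }
  sel <- match(variables, states$vars)
  if (states$form == "materialized") {
    mag <- states$mag[, sel, drop = FALSE]
    deriv <- states$deriv[, sel, drop = FALSE]
    key <- encode_state_keys(mag, deriv)
    keep <- !duplicated(key)
    return(new_states_materialized(variables,
                                   mag[keep, , drop = FALSE],
                                   deriv[keep, , drop = FALSE]))
  }
  mag <- states$mag[, sel, drop = FALSE]
  dset <- states$dset[, sel, drop = FALSE]
  bk <- paste(encode_state_keys(mag, matrix(1L, nrow(mag), ncol(mag))),
              apply(dset, 1L, paste, collapse = ""))
  keep <- !duplicated(bk)
  keys <- materialize_keys(mag[keep, , drop = FALSE],
                           dset[keep, , drop = FALSE])
  d <- decode_state_keys(keys, length(variables))
  new_states_materialized(variables, d$mag, d$deriv)
}

#' @export
print.qml_states <- function(x, ...) {
  cat("<qualitative states> ", state_count(x), " states over ",
      length(x$vars), " variables (", x$form, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.qml_states <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  x <- materialize_states(x)
  cells <- lapply(seq_along(x$vars), function(i) {
    paste(ifelse(x$mag[, i], "pos", "zer"),
          SIGN_LEVELS[x$deriv[, i]], sep = ",")
  })
  out <- as.data.frame(stats::setNames(cells, x$vars),
                       check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(row.names)) rownames(out) <- row.names
  out
}

#' Build a state set from a table of sign pairs
#'
#' The table layout mirrors the exported TSV: one row per state, one column
#' per variable, each cell a `"magnitude,derivative"` pair such as
#' `"zer,pos"`.
#'
#' @param df a data.frame of `"mag,deriv"` cells, columns named by variable.
#' @return a materialized `qml_states`.
#' @export
states_from_table <- function(df) {
  vars <- colnames(df)
  n <- nrow(df)
  mag <- matrix(FALSE, n, length(vars))
  deriv <- matrix(0L, n, length(vars))
  for (i in seq_along(vars)) {
    parts <- strsplit(trimws(as.character(df[[i]])), ",")
    m <- vapply(parts, `[`, character(1L), 1L)
    d <- vapply(parts, `[`, character(1L), 2L)
    m <- trimws(m); d <- trimws(d)
    if (!all(m %in% c("zer", "pos"))) stop("magnitudes must be zer or pos")
    if (!all(d %in% SIGN_LEVELS)) stop("derivatives must be neg/zer/pos")
    mag[, i] <- m == "pos"
    deriv[, i] <- match(d, SIGN_LEVELS)
  }
  key <- encode_state_keys(mag, deriv)
  keep <- !duplicated(key)
  new_states_materialized(vars, mag[keep, , drop = FALSE],
                          deriv[keep, , drop = FALSE])
}

#' Write / read a state set as TSV
#'
#' One row per state, one column per variable, cells `"mag,deriv"`.
#'
#' @param states a `qml_states` object.
#' @param path file path.
#' @return `write_states_tsv()` returns `path` invisibly; `read_states_tsv()`
#'   a materialized `qml_states`.
#' @export
write_states_tsv <- function(states, path) {
  utils::write.table(as.data.frame(states), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_tsv
#' @export
read_states_tsv <- function(path) {
  states_from_table(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      colClasses = "character"))
}
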