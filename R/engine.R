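# Internal evaluation engine.
#
# Fitness only needs the generated state set projected onto the variables
# shared with the target. Flux signs depend solely on magnitudes, so the
# projection is computed by enumerating magnitude assignments over the
# *relevant* variables only: the shared variables plus the inputs of every
# transition touching a shared variable. Magnitudes of all other variables
# never change the projected set (their derivative sets are always
# non-empty, so every assignment extends to a full state).

DSET_MASK <- c(2L, 4L, 1L, 7L)  # bit 1 = neg, bit 2 = zer, bit 4 = pos
POPCOUNT8 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L)

# Factored blocks of the model's state set projected onto `shared`
# (deduplicated): list(mag, dset, magkey).
projected_blocks <- function(qde, shared,
                             cap = getOption("qmlearn.enum_cap", 22L)) {
  shared_idx <- match(shared, qde$variables)
  touch_t <- sort(unique(unlist(lapply(shared_idx, function(vi) {
    qde$constraints[[vi]]$transition
  }))))
  rel <- sort(unique(c(shared_idx,
                       unlist(lapply(qde$transitions[touch_t],
                                     `[[`, "inputs")))))
  if (length(rel) > cap) {
    stop("relevant-variable set of size ", length(rel),
         " exceeds the enumeration cap of ", cap)
  }
  n <- length(shared)
  cols <- match(shared_idx, rel)
  w2 <- 2 ^ (seq_len(n) - 1L)
  w4 <- 4 ^ (seq_len(n) - 1L)
  keys <- numeric(0L)
  enum_fold(qde, rel, shared_idx, function(mag, dset) {
    magkey <- as.vector(mag[, cols, drop = FALSE] %*% w2)
    codekey <- as.vector((dset - 1L) %*% w4)
    keys <<- unique(c(keys, magkey * 4 ^ n + codekey))
  })
  magkey <- floor(keys / 4 ^ n)
  codekey <- keys - magkey * 4 ^ n
  mag <- matrix(FALSE, length(keys), n)
  dset <- matrix(0L, length(keys), n)
  for (i in seq_len(n)) {
    mag[, i] <- floor(magkey / 2 ^ (i - 1L)) %% 2 == 1
    dset[, i] <- as.integer(floor(codekey / 4 ^ (i - 1L)) %% 4 + 1)
  }
  list(mag = mag, dset = dset, magkey = magkey)
}

# Size of the union of derivative-set boxes (rows of a dset matrix) over the
# same magnitude assignment. Inclusion-exclusion for few boxes, explicit
# expansion otherwise.
union_boxes <- function(dset) {
  dset <- dset[!duplicated(apply(dset, 1L, paste, collapse = "")), ,
               drop = FALSE]
  k <- nrow(dset)
  if (k == 1L) return(prod(DSET_SIZE[dset[1L, ]]))
  masks <- matrix(DSET_MASK[dset], k, ncol(dset))
  if (k <= 12L) {
    total <- 0
    for (s in seq_len(2 ^ k - 1L)) {
      sel <- which(bitwAnd(s, 2 ^ (seq_len(k) - 1L)) > 0L)
      m <- masks[sel[1L], ]
      for (j in sel[-1L]) m <- bitwAnd(m, masks[j, ])
      if (any(m == 0L)) next
      total <- total + (-1) ^ (length(sel) + 1L) * prod(POPCOUNT8[m + 1L])
    }
    return(total)
  }
  keys <- lapply(seq_len(k), function(r) {
    kk <- 0
    for (v in seq_len(ncol(dset))) {
      opts <- which(bitwAnd(masks[r, v], c(1L, 2L, 4L)) > 0L) - 1L
      kk <- as.vector(outer(kk, opts * 3 ^ (v - 1L), "+"))
    }
    kk
  })
  length(unique(unlist(keys)))
}

dset_member <- function(code, dcode) {
  if (code == 4L) return(rep(TRUE, length(dcode)))
  if (code == 1L) return(dcode == 2L)
  if (code == 2L) return(dcode == 3L)
  dcode == 1L
}

# Count of target states covered by the blocks, and the projected set size.
block_target_counts <- function(blocks, tmag, tderiv) {
  n <- ncol(tmag)
  tmagkey <- as.vector(tmag %*% (2 ^ (seq_len(n) - 1L)))
  bsplit <- split(seq_along(blocks$magkey), blocks$magkey)
  tsplit <- split(seq_along(tmagkey), tmagkey)
  inter <- 0L
  size <- 0
  for (mk in names(bsplit)) {
    rows <- bsplit[[mk]]
    size <- size + union_boxes(blocks$dset[rows, , drop = FALSE])
    trows <- tsplit[[mk]]
    if (is.null(trows)) next
    covered <- rep(FALSE, length(trows))
    for (b in rows) {
      todo <- which(!covered)
      if (length(todo) == 0L) break
      memb <- rep(TRUE, length(todo))
      for (v in seq_len(n)) {
        memb <- memb & dset_member(blocks$dset[b, v],
                                   tderiv[trows[todo], v])
      }
      covered[todo[memb]] <- TRUE
    }
    inter <- inter + sum(covered)
  }
  list(intersection = inter, generated = size)
}

# Fitness of a model against target states; comparison is over the variables
# shared by model and target, per the evaluation contract. `cache` (an
# environment) memoizes target projections by shared-variable subset.
eval_model_fitness <- function(model, target, base = 6, cache = NULL) {
  shared <- intersect(model$places, target$vars)
  if (length(shared) == 0L) {
    return(list(discarded = TRUE, f1 = 0, f2 = 0, F = 0,
                shared = character(0L), qsg = 0, qst = 0))
  }
  shared <- target$vars[target$vars %in% shared]  # stable order
  tkey <- paste(shared, collapse = "\r")
  tproj <- if (!is.null(cache) && !is.null(cache[[tkey]])) {
    cache[[tkey]]
  } else {
    p <- project_states(target, shared)
    if (!is.null(cache)) cache[[tkey]] <- p
    p
  }
  qde <- derive_qde(model)
  blocks <- projected_blocks(qde, shared)
  cnt <- block_target_counts(blocks, tproj$mag, tproj$deriv)
  qst <- length(tproj$key)
  U <- base ^ length(shared)
  f1 <- cnt$intersection / qst
  denom <- U - qst
  f2 <- if (denom > 0) (cnt$generated - cnt$intersection) / denom else 0
  list(discarded = FALSE, f1 = f1, f2 = f2, F = combine_fitness(f1, f2),
       shared = shared, qsg = cnt$generated, qst = qst)
}

# Exact number of consistent states over the model's own variables, without
# materialization: sum over magnitude assignments of the product of
# derivative-set sizes. Library-shaped models use a factorized count; the
# generic path enumerates the input variables directly.
own_state_count <- function(model, cap = getOption("qmlearn.enum_cap", 22L)) {
  qde <- derive_qde(model)
  fast <- fast_library_count(qde)
  if (!is.null(fast)) return(fast)
  rel <- sort(unique(unlist(lapply(qde$transitions, `[[`, "inputs"))))
  if (length(rel) > cap) {
    stop("input-variable set of size ", length(rel),
         " exceeds the enumeration cap of ", cap)
  }
  nfree_other <- length(qde$variables) - length(rel)
  total <- 0
  enum_fold(qde, rel, seq_along(qde$variables), function(mag, dset) {
    total <<- total + sum(3 ^ rowSums(dset == 4L))
  })
  total * 2 ^ nfree_other
}

# Factorized state count for library-shaped models, where every transition
# either has only primitive inputs ("det": its flux is determined by the
# base magnitudes) or exactly one complex input. Conditional on the base
# magnitudes, each complex's magnitude influences only its own derivative
# set and the ("has positive influence") disjunctions of the base variables
# its unbindings produce, so the sum over complex magnitudes collapses to a
# subset dynamic program over the conditionally-relevant base variables.
# Returns NULL when the model does not have this shape.
fast_library_count <- function(qde) {
  vars <- qde$variables
  nv <- length(vars)
  cx <- is_complex(vars)
  ins <- lapply(qde$transitions, `[[`, "inputs")
  outs <- lapply(qde$transitions, `[[`, "outputs")
  det_t <- which(vapply(ins, function(ii) all(!cx[ii]), logical(1L)))
  non_t <- setdiff(seq_along(ins), det_t)
  for (t in non_t) {
    if (length(ins[[t]]) != 1L || !cx[ins[[t]]]) return(NULL)
  }
  C <- sort(unique(unlist(ins[non_t])))
  # complexes must not produce other enumerated complexes
  for (t in non_t) if (any(outs[[t]] %in% C)) return(NULL)
  B <- sort(unique(unlist(ins[det_t])))
  # the base loop is scalar; beyond ~10 base variables the vectorized
  # generic enumeration wins
  if (length(B) > 10L) return(NULL)
  pure <- setdiff(seq_len(nv), c(B, C))
  # static incidence: which base variables each complex produces (via its
  # unbindings), and which det transitions produce/consume each variable
  prod_by_cx <- matrix(FALSE, length(C), length(B))
  for (t in non_t) {
    ci <- match(ins[[t]], C)
    bo <- match(outs[[t]], B)
    prod_by_cx[ci, bo[!is.na(bo)]] <- TRUE
  }
  nB <- length(B)
  nC <- length(C)
  ndet <- length(det_t)
  det_in <- lapply(ins[det_t], function(ii) match(ii, B))
  det_out <- outs[det_t]
  total <- 0
  for (bm in seq_len(2 ^ nB) - 1L) {
    magB <- bitwAnd(bm, 2 ^ (seq_len(nB) - 1L)) > 0L
    flag <- vapply(det_in, function(ii) all(magB[ii]), logical(1L))
    # per-variable determined influences from det transitions
    det_pos <- rep(FALSE, nv); det_neg <- rep(FALSE, nv)
    for (k in seq_len(ndet)) {
      if (!flag[[k]]) next
      det_neg[B[det_in[[k]]]] <- TRUE
      det_pos[det_out[[k]]] <- TRUE
    }
    # base variables: consumed only by det transitions; produced by det
    # transitions and/or by complexes' unbindings
    const3 <- 0L
    cond <- integer(0L)  # indices into B with outcome riding on complexes
    for (j in seq_len(nB)) {
      v <- B[[j]]
      if (!det_neg[[v]]) next               # never negative: size 1
      if (det_pos[[v]]) { const3 <- const3 + 1L; next }
      if (any(prod_by_cx[, j])) cond <- c(cond, j)
    }
    k <- length(cond)
    # subset DP over complexes: state = conditional base vars already
    # covered by some positive complex
    dp <- numeric(2 ^ k); dp[1L] <- 1
    ss <- seq_len(2 ^ k) - 1L
    for (ci in seq_len(nC)) {
      w1 <- if (det_pos[[C[[ci]]]]) 3 else 1  # complex's own deriv set
      mask <- 0L
      if (k > 0L) {
        hits <- which(prod_by_cx[ci, cond])
        if (length(hits) > 0L) mask <- sum(2 ^ (hits - 1L))
      }
      if (mask == 0L) {
        dp <- dp * (1 + w1)
      } else {
        contrib <- rowsum(dp * w1, bitwOr(ss, mask))
        dp[as.integer(rownames(contrib)) + 1L] <-
          dp[as.integer(rownames(contrib)) + 1L] + contrib[, 1L]
      }
    }
    pc <- vapply(ss, function(s) sum(bitwAnd(s, 2 ^ (seq_len(max(k, 1L)) - 1L)) > 0L),
                 numeric(1L))
    total <- total + 3 ^ const3 * sum(dp * 3 ^ pc)
  }
  total * 2 ^ length(pure)
}
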