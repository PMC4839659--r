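# Exhaustive-enumeration oracle for the folding engine. Kept independent of
# the C++ dynamic program: structures are generated recursively and scored by
# structure_energy(), an R reimplementation of the energy model.

.fold_const <- list(
  v = c(AU = -1.1, UA = -1.1, GC = -2.2, CG = -2.2, GU = -0.8, UG = -0.8),
  hairpin_base = 4.5, hairpin_per_nt = 0.3,
  loop_base = 2.0, loop_per_nt = 0.5,
  ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
  min_hairpin = 3L
)

.pair_name <- function(a, b) {
  key <- paste0(a, b)
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (key %in% ok) key else NA_character_
}

.seq_chars <- function(seq) {
  up <- gsub("T", "U", toupper(seq), fixed = TRUE)
  strsplit(up, "")[[1]]
}

#' Energy of a given secondary structure under the embedded model
#'
#' Scores an explicit set of base pairs with the same constants as the DP
#' engine: stacks are additive pair stabilities, hairpin and interior loops
#' carry linear penalties, multiloops an affine penalty. Used as the
#' independent scorer behind [enumerate_min_energy()].
#'
#' @param seq RNA/DNA string.
#' @param pairs two-column matrix of 1-based paired positions (i < j), or an
#'   empty matrix / NULL for the open chain.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, pairs) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (is.null(pairs) || NROW(pairs) == 0L) return(0)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  partner <- integer(n)
  for (r in seq_len(nrow(pairs))) {
    i <- min(pairs[r, ]); j <- max(pairs[r, ])
    pn <- .pair_name(ch[i], ch[j])
    if (is.na(pn)) stop("non-pairable bases at (", i, ",", j, ")")
    if (j - i - 1 < .fold_const$min_hairpin) stop("hairpin loop below minimum")
    partner[i] <- j; partner[j] <- i
  }
  cst <- .fold_const
  pv <- function(i) cst$v[[.pair_name(ch[i], ch[partner[i]])]]

  # direct children of the loop closed by (i,j); i=0,j=n+1 for exterior
  children <- function(i, j) {
    kids <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    kids
  }

  score_pair <- function(i, j) {
    kids <- children(i, j)
    span_inside <- j - i - 1L
    e <- 0
    if (length(kids) == 0L) {
      e <- cst$hairpin_base + cst$hairpin_per_nt * (span_inside - cst$min_hairpin)
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      u1 <- k - i - 1L; u2 <- j - l - 1L
      if (u1 == 0L && u2 == 0L) {
        e <- pv(i) + pv(k)
      } else {
        e <- cst$loop_base + cst$loop_per_nt * (u1 + u2)
      }
    } else {
      unp <- span_inside - sum(vapply(kids, function(p) p[2] - p[1] + 1L, integer(1)))
      e <- cst$ml_close + cst$ml_branch * (length(kids) + 1L) + cst$ml_unpaired * unp
    }
    for (kid in kids) e <- e + score_pair(kid[1], kid[2])
    e
  }

  tops <- children(0L, n + 1L)
  sum(vapply(tops, function(p) score_pair(p[1], p[2]), numeric(1)))
}

# All non-crossing pair sets over [i, j] (memoized per call).
.enumerate_structures <- function(ch) {
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)  # i unpaired
    for (k in seq.int(i + .fold_const$min_hairpin + 1L, j, length.out = max(0, j - (i + .fold_const$min_hairpin + 1L) + 1L))) {
      k <- as.integer(k)
      if (is.na(.pair_name(ch[i], ch[k]))) next
      inner <- rec(i + 1L, k - 1L)
      after <- rec(k + 1L, j)
      for (s1 in inner) for (s2 in after) {
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Exact minimum-energy structure by exhaustive enumeration (test oracle)
#'
#' Enumerates every non-crossing structure of a short sequence and scores
#' each with [structure_energy()]. Ties break toward fewer pairs, then the
#' lexicographically smallest dot-bracket. Refuses sequences over 18 nt
#' (combinatorial blow-up); the DP engine is for real inputs.
#'
#' @param seq RNA/DNA string of at most 18 nt.
#' @return `fold_result` with the exact minimum.
#' @export
enumerate_min_energy <- function(seq) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (n > 18L) stop("enumerate_min_energy refuses sequences > 18 nt")
  structs <- .enumerate_structures(ch)
  energies <- vapply(structs, function(p) structure_energy(seq, p), numeric(1))
  energies <- round(energies, 9)
  best_e <- min(energies, 0)
  cand <- which(energies == best_e)
  npairs <- vapply(structs[cand], NROW, integer(1))
  cand <- cand[npairs == min(npairs)]
  dbs <- vapply(structs[cand], function(p) .pairs_to_db(p, n), character(1))
  pick <- cand[order(dbs)][1]
  partner <- integer(n)
  p <- structs[[pick]]
  if (NROW(p) > 0) for (r in seq_len(nrow(p))) {
    partner[p[r, 1]] <- p[r, 2]; partner[p[r, 2]] <- p[r, 1]
  }
  structure(
    list(sequence = toupper(seq), structure = .pairs_to_db(p, n),
         energy = best_e, partner = partner),
    class = "fold_result"
  )
}

.pairs_to_db <- function(pairs, n) {
  db <- rep(".", n)
  if (NROW(pairs) > 0) for (r in seq_len(nrow(pairs))) {
    i <- min(pairs[r, ]); j <- max(pairs[r, ])
    db[i] <- "("; db[j] <- ")"
  }
  paste(db, collapse = "")
}

# Independent duplex oracle: memoized recursion over all monotone
# intermolecular matchings (pure R, distinct decomposition from the C++ DP).
duplex_energy_oracle <- function(a, b) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  n <- length(ca); m <- length(cb)
  cst <- .fold_const
  memo <- new.env(parent = emptyenv())
  # best additional energy given the previous pair was (pi, pj)
  rec <- function(pi, pj) {
    key <- paste0(pi, ":", pj)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0
    for (i in seq.int(pi + 1L, n, length.out = max(0, n - pi))) {
      for (j in seq.int(pj - 1L, 1L, length.out = max(0, pj - 1L))) {
        i <- as.integer(i); j <- as.integer(j)
        pn <- .pair_name(ca[i], cb[j])
        if (is.na(pn)) next
        u1 <- i - pi - 1L; u2 <- pj - j - 1L
        cost <- if (pi >= 1L && u1 == 0L && u2 == 0L) {
          cst$v[[.pair_name(ca[pi], cb[pj])]] + cst$v[[pn]]
        } else if (pi >= 1L) {
          cst$loop_base + cst$loop_per_nt * (u1 + u2)
        } else 0
        e <- cost + rec(i, j)
        if (e < best) best <- e
      }
    }
    memo[[key]] <- best
    best
  }
  rec(0L, m + 1L)
}
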