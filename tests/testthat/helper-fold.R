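# Independent brute-force oracle for the folding energy model: enumerate all
# nested structures (min hairpin 3) and score them by loop decomposition.
# Written against the documented model, not against the DP code.

enum_structures <- function(n) {
  rec <- function(i, j) {
    if (j - i + 1 < 5) return(list(list()))
    out <- rec(i + 1, j)                      # i unpaired
    for (k in (i + 4):j) {
      inner <- rec(i + 1, k - 1)
      right <- if (k + 1 > j) list(list()) else rec(k + 1, j)
      for (a in inner) for (b in right)
        out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  rec(1, n)
}

oracle_pairable <- function(a, b)
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")

# energy of one structure by loop decomposition; NA when invalid
oracle_energy <- function(seq, pairs, pars) {
  ch <- strsplit(seq, "")[[1]]
  if (!length(pairs)) return(0)
  P <- do.call(rbind, pairs)
  for (r in seq_len(nrow(P)))
    if (!oracle_pairable(ch[P[r, 1]], ch[P[r, 2]])) return(NA_real_)
  par <- pars$par; S <- pars$stack
  partner <- rep(NA_integer_, length(ch))
  partner[P[, 1]] <- P[, 2]; partner[P[, 2]] <- P[, 1]
  E <- 0
  for (r in seq_len(nrow(P))) {
    i <- P[r, 1]; j <- P[r, 2]
    k <- i + 1; children <- list(); u <- 0
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k && partner[k] < j) {
        children[[length(children) + 1]] <- c(k, partner[k])
        k <- partner[k] + 1
      } else { u <- u + 1; k <- k + 1 }
    }
    nc <- length(children)
    if (nc == 0) {
      if (u < 3) return(NA_real_)
      E <- E + par[["hairpin_a"]] + par[["hairpin_b"]] * u
    } else if (nc == 1) {
      p <- children[[1]][1]; q <- children[[1]][2]
      u1 <- p - i - 1; u2 <- j - q - 1
      if (u1 == 0 && u2 == 0) {
        E <- E + S[paste0(ch[i], ch[j]), paste0(ch[p], ch[q])]
      } else {
        if (u1 + u2 > par[["maxloop"]]) return(NA_real_)
        E <- E + par[["interior_a"]] + par[["interior_b"]] * (u1 + u2)
      }
    } else {
      E <- E + par[["multi_a"]] + par[["multi_b"]] * (nc + 1) +
        par[["multi_c"]] * u
    }
  }
  E
}

oracle_mfe <- function(seq, pars) {
  es <- vapply(enum_structures(nchar(seq)), function(p) {
    e <- oracle_energy(seq, p, pars)
    if (is.na(e)) Inf else e
  }, 1.0)
  min(0, es)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
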