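# Independent brute-force oracles used to cross-check the package's
# implementations. These are written against the rule definitions directly
# and share no code with the implementation paths they verify.

# ---- exhaustive two-sided Fisher p by hypergeometric enumeration ----------
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p0 <- pr[xs == a]
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# ---- asymptotic two-sided Kolmogorov p from the Kolmogorov series ---------
ks_asymptotic <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  D <- max(abs(Fx - Fy))
  t <- sqrt(nx * ny / (nx + ny)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(D = D, p = max(0, min(1, p)))
}

# ---- clause-by-clause brute-force motif matcher ---------------------------
# Enumerates every SSE tuple and re-checks each clause of the motif
# definition from the interaction matrix, with its own side-plane fit.
brute_force_rlm <- function(im, s) {
  el <- im@sse@elements
  n <- nrow(el)
  codes <- im@codes
  ca_of <- function(k) {
    a <- s@atoms
    sel <- !a$het & a$chain == el$chain[k] & a$atom == "CA" &
      a$resno >= el$start[k] & a$resno <= el$end[k]
    as.matrix(a[sel, c("x", "y", "z")])
  }
  side_of <- function(k, strands) {
    ca <- do.call(rbind, lapply(strands, ca_of))
    ctr <- colMeans(ca)
    x <- sweep(ca, 2, ctr)
    nrm <- svd(x)$v[, 3]
    sign(sum((colMeans(ca_of(k)) - ctr) * nrm))
  }
  results <- list()
  for (i in seq_len(n)) for (ii in seq_len(n)) for (iii in seq_len(n)) {
    if (!(i < ii && ii < iii)) next
    if (ii != i + 1L || iii != ii + 1L) next       # first wind: no insertions
    if (el$kind[i] != "strand" || el$nres[i] < 3) next
    if (el$kind[ii] != "helix") next
    if (el$kind[iii] != "strand" || el$nres[iii] < 3) next
    if (codes[i, iii] != "P") next
    if (!codes[i, ii] %in% c("C", "T")) next
    for (v in seq_len(n)) {
      if (v <= iii) next
      if (el$kind[v] != "strand" || el$nres[v] < 3) next
      if (codes[i, v] != "P") next
      sII <- side_of(ii, c(i, iii, v))
      if (sII == 0) next
      cands <- list()
      for (m4 in seq_len(n)) {
        if (!(m4 > iii && m4 < v)) next
        if (el$kind[m4] == "helix") {
          if ((codes[m4, i] %in% c("C", "T") ||
               codes[m4, v] %in% c("C", "T")) &&
              side_of(m4, c(i, iii, v)) == -sII)
            cands[[length(cands) + 1]] <- list(iv = m4, var = "helix-IV")
        } else {
          cands[[length(cands) + 1]] <- list(iv = m4, var = "strand-IV")
        }
      }
      n_between <- sum(seq_len(n) > iii & seq_len(n) < v)
      if (length(cands) == 0 && n_between == 0) {
        gap <- el$start[v] - el$end[iii] - 1L
        if (gap >= 2) cands[[1]] <- list(iv = NA, var = "loop-IV")
      }
      if (length(cands) == 0) next
      pri <- c("helix-IV" = 1, "strand-IV" = 2, "loop-IV" = 3)
      sc <- vapply(cands, function(cc)
        pri[[cc$var]] * 1000 - ifelse(is.na(cc$iv), 0, cc$iv), numeric(1))
      best <- cands[[which.min(sc)]]
      results[[length(results) + 1]] <-
        list(I = i, II = ii, III = iii, IV = best$iv, V = v,
             variant = best$var)
    }
  }
  results
}

# canonical signature of matches for comparison
match_signature <- function(matches) {
  sort(vapply(matches, function(m) {
    idx <- m@sseIndices
    sprintf("%d/%d/%d/%s/%d:%s", idx[["I"]], idx[["II"]], idx[["III"]],
            if ("IV" %in% names(idx)) as.character(idx[["IV"]]) else "NA",
            idx[["V"]], m@variant)
  }, character(1)))
}

oracle_signature <- function(oracle) {
  sort(vapply(oracle, function(m)
    sprintf("%d/%d/%d/%s/%d:%s", m$I, m$II, m$III,
            if (is.na(m$IV)) "NA" else as.character(m$IV), m$V, m$variant),
    character(1)))
}

# ---- piecewise-constant binning oracle ------------------------------------
bin_oracle <- function(v, B) {
  L <- length(v)
  vapply(seq_len(B), function(i) {
    pos <- (i - 0.5) * L / B
    v[min(L, floor(pos) + 1)]
  }, numeric(1))
}
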